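# Internal helpers shared across modules.

STRESS_NAMES <- c("acidity", "aridity", "heat", "salinity")

#' Evaluate code with a temporarily fixed RNG state
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded helpers do not perturb the global random stream.
#' With `seed = NULL` the code runs on the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # initialise the stream so we can save it
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a stage seed from a master seed; kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483629L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    stopf("'%s' must be a single integer >= %d", name, min)
  }
  invisible(as.integer(x))
}

assert_prob <- function(x, name, open = TRUE) {
  ok <- length(x) == 1L && is.finite(x) &&
    if (open) (x > 0 && x < 1) else (x >= 0 && x <= 1)
  if (!ok) stopf("'%s' must be a probability %s", name,
                 if (open) "in (0, 1)" else "in [0, 1]")
  invisible(x)
}

# Columns of a stress-profile table as a matrix keyed by sample_id.
stress_matrix <- function(stress) {
  miss <- setdiff(c("sample_id", STRESS_NAMES), names(stress))
  if (length(miss)) stopf("stress table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  m <- as.matrix(stress[, STRESS_NAMES, drop = FALSE])
  rownames(m) <- as.character(stress$sample_id)
  storage.mode(m) <- "double"
  m
}
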