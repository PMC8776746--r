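# Strain x gene copy-count matrix: construction, gene classification,
# richness and per-soil-sample pangenome diversity.

#' Construct a pangenome matrix
#'
#' Wraps a strain x gene matrix of orthologous gene-cluster copy counts.
#' Presence is derived as `count >= 1`; copy counts are preserved for the
#' duplication trait.
#'
#' @param counts Numeric matrix, strains in rows, genes in columns, with
#'   non-negative integer entries; must carry dimnames.
#' @param labels Optional gene label vector (see [classify_genes()]).
#' @return A `pangenome_matrix` object (list with `counts`, `strains`,
#'   `genes`, `labels`).
#' @export
pangenome_matrix <- function(counts, labels = NULL) {
  if (!is.matrix(counts)) stopf("'counts' must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stopf("'counts' must have strain rownames and gene colnames")
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stopf("'counts' must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  structure(list(counts = counts,
                 strains = rownames(counts),
                 genes = colnames(counts),
                 labels = labels),
            class = "pangenome_matrix")
}

#' @export
print.pangenome_matrix <- function(x, ...) {
  cat(sprintf("pangenome_matrix: %d strains x %d genes\n",
              nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$labels)) {
    print(table(x$labels))
  } else cat("(genes not yet classified)\n")
  invisible(x)
}

#' Presence/absence view of a pangenome matrix
#'
#' @param pm A `pangenome_matrix`.
#' @return Logical strain x gene matrix, `TRUE` where copy count >= 1.
#' @export
presence <- function(pm) {
  stopifnot(inherits(pm, "pangenome_matrix"))
  pm$counts >= 1L
}

#' Classify genes as core, accessory or singleton
#'
#' A gene is *core* when its presence frequency across strains is at least
#' `core_threshold` (default 0.99), *singleton* when present in exactly one
#' strain, and *accessory* otherwise.
#'
#' @param pm A `pangenome_matrix`.
#' @param core_threshold Presence-frequency threshold for the core label.
#' @return The matrix with `labels` filled in (named character vector).
#' @export
classify_genes <- function(pm, core_threshold = 0.99) {
  stopifnot(inherits(pm, "pangenome_matrix"))
  n <- nrow(pm$counts)
  if (n < 2L) stopf("need at least 2 strains to classify genes")
  if (ncol(pm$counts) == 0L) stopf("empty pangenome matrix")
  pres <- presence(pm)
  npres <- colSums(pres)
  freq <- npres / n
  lab <- rep("accessory", length(freq))
  lab[freq >= core_threshold] <- "core"
  lab[npres == 1L] <- "singleton"
  names(lab) <- pm$genes
  pm$labels <- lab
  pm
}

#' Drop singletons and ubiquitous genes before richness analysis
#'
#' Removes singleton genes (present in exactly one strain) and genes present
#' in at least `ubiquity_threshold` of strains (default 1, i.e. present in
#' every strain). The ubiquity filter is deliberately distinct from the 99%
#' core *label*: both thresholds are exposed because they answer different
#' questions (designating the core genome vs removing genes carrying no
#' between-strain information).
#'
#' @param pm A labelled `pangenome_matrix` (see [classify_genes()]).
#' @param ubiquity_threshold Presence frequency at or above which a gene is
#'   dropped as uninformative.
#' @return Filtered `pangenome_matrix` (labels subset accordingly).
#' @export
filter_for_richness <- function(pm, ubiquity_threshold = 1) {
  stopifnot(inherits(pm, "pangenome_matrix"))
  if (is.null(pm$labels)) stopf("classify genes before filtering")
  pres <- presence(pm)
  npres <- colSums(pres)
  keep <- npres > 1L & npres / nrow(pres) < ubiquity_threshold
  if (!any(keep)) warnf("all genes removed by the richness filter")
  pm$counts <- pm$counts[, keep, drop = FALSE]
  pm$genes <- colnames(pm$counts)
  pm$labels <- pm$labels[keep]
  pm
}

#' Per-strain gene richness
#'
#' Number of distinct genes present in each strain, computed on a filtered
#' matrix (singletons and ubiquitous genes removed).
#'
#' @param pm A `pangenome_matrix`.
#' @return Data frame with columns `strain_id`, `richness`.
#' @export
gene_richness <- function(pm) {
  stopifnot(inherits(pm, "pangenome_matrix"))
  data.frame(strain_id = pm$strains,
             richness = as.integer(rowSums(presence(pm))),
             stringsAsFactors = FALSE)
}

#' Per-soil-sample pangenome diversity
#'
#' Number of distinct genes present in at least one member strain of each
#' soil sample (a set union over strains, not a sum of richness).
#'
#' @param pm A `pangenome_matrix`.
#' @param design Data frame mapping `strain_id` to `sample_id`.
#' @return Data frame with columns `sample_id`, `diversity`.
#' @export
pangenome_diversity <- function(pm, design) {
  stopifnot(inherits(pm, "pangenome_matrix"))
  if (!all(c("strain_id", "sample_id") %in% names(design))) {
    stopf("'design' needs strain_id and sample_id columns")
  }
  idx <- match(pm$strains, design$strain_id)
  if (anyNA(idx)) {
    stopf("strain(s) not mapped to a soil sample: %s",
          paste(utils::head(pm$strains[is.na(idx)], 5), collapse = ", "))
  }
  samp <- as.character(design$sample_id)[idx]
  pres <- presence(pm)
  res <- vapply(split(seq_along(samp), samp), function(rows) {
    if (length(rows) == 1L) sum(pres[rows, ]) else sum(colSums(pres[rows, , drop = FALSE]) > 0L)
  }, integer(1))
  data.frame(sample_id = names(res), diversity = as.integer(res),
             stringsAsFactors = FALSE)
}
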