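# Gaussian-process smoothing of per-gene statistics along a circular
# chromosome, retention-hotspot detection and core-gene density tracks.
#
# The cyclic covariance is a Matern-3/2 kernel evaluated on the circular
# (shortest-arc) distance, with a white-noise nugget. Hyperparameters are
# chosen by profile marginal-likelihood maximization (the marginal variance
# has a closed-form profile), with a fixed-range fallback when the search
# fails. Credible bands are GP predictive intervals for the latent mean.

#' Construct / validate a genome map
#'
#' @param entries Data frame `gene_id`, `position` (bp, 0-based half-open),
#'   `label` (`core` / `accessory`).
#' @param genome_length Circular genome length in bp.
#' @return A `genome_map` data frame with a `genome_length` attribute.
#' @export
genome_map <- function(entries, genome_length) {
  need <- c("gene_id", "position", "label")
  if (!all(need %in% names(entries))) {
    stopf("genome map needs columns %s", paste(need, collapse = ", "))
  }
  if (genome_length <= 0) stopf("'genome_length' must be positive")
  if (any(entries$position < 0 | entries$position >= genome_length)) {
    stopf("positions must lie in [0, genome_length) — coordinates are 0-based, half-open")
  }
  if (anyDuplicated(entries$position)) stopf("positions must be unique")
  if (!all(entries$label %in% c("core", "accessory"))) {
    stopf("labels must be 'core' or 'accessory'")
  }
  structure(as.data.frame(entries), genome_length = genome_length,
            class = c("genome_map", "data.frame"))
}

#' Shortest-arc distance on a circular genome
#'
#' `min(|a - b|, L - |a - b|)` for positions in `[0, L)`. Vectorized with
#' recycling.
#'
#' @param a,b Positions in bp.
#' @param L Genome length in bp.
#' @return Distances in bp.
#' @export
circular_distance <- function(a, b, L) {
  if (any(a < 0 | a >= L) || any(b < 0 | b >= L)) {
    stopf("positions must lie in [0, L)")
  }
  d <- abs(a - b)
  pmin(d, L - d)
}

# Matern-3/2 correlation at distance d with range rho.
matern32 <- function(d, rho) {
  s <- sqrt(3) * d / rho
  (1 + s) * exp(-s)
}

# Cross-correlation matrix on the circle (positions may equal L for the
# periodic grid endpoint, which is identified with 0).
circ_corr <- function(p1, p2, L, rho) {
  d <- abs(outer(p1 %% L, p2 %% L, "-"))
  matern32(pmin(d, L - d), rho)
}

chol_jitter <- function(M) {
  jit <- 0
  for (e in c(0, 10^(-8:-2))) {
    ch <- try(chol(M + diag(e, nrow(M))), silent = TRUE)
    if (!inherits(ch, "try-error")) return(ch)
  }
  NULL
}

# Negative profile log marginal likelihood over (log rho, log tau), where
# tau = noise_sd / marginal_sd; the marginal variance is profiled out.
gp_profile_nll <- function(lpar, Dcor_fun, yc, n) {
  rho <- exp(lpar[1]); tau2 <- exp(2 * lpar[2])
  Ct <- Dcor_fun(rho)
  diag(Ct) <- diag(Ct) + tau2 + 1e-8
  ch <- chol_jitter(Ct)
  if (is.null(ch)) return(1e10)
  a <- backsolve(ch, backsolve(ch, yc, transpose = TRUE))
  s2 <- sum(yc * a) / n
  if (!is.finite(s2) || s2 < 0) return(1e10)
  n / 2 * log(max(s2, 1e-300)) + sum(log(diag(ch)))
}

#' Fit a cyclic Gaussian-process smoother on the genome
#'
#' Smooths per-gene statistics (z-scores or traits) along the circular
#' chromosome with a Matern-3/2 GP on circular distance plus a white-noise
#' nugget, returning the posterior mean and 95% band of the latent smooth
#' on a regular grid. Hyperparameters (range, marginal SD, noise SD) are
#' estimated by profile marginal-likelihood maximization with range bounded
#' in `[L/500, L/2]`; a non-convergent search falls back to a fixed range of
#' `L/20` with a flag. The track is periodic: predictions at 0 and L
#' coincide.
#'
#' @param map A `genome_map` (or data frame with `position`).
#' @param values Named (by gene_id) or positional statistic vector.
#' @param grid_step Grid spacing in bp (default `genome_length / 2000`).
#' @param max_points Genes are subsampled to this many for the GP fit
#'   (seeded), keeping the dense linear algebra tractable.
#' @param hyper Optional fixed hyperparameters, a list with `range` and
#'   `noise_ratio` (noise SD / marginal SD); skips optimization.
#' @param seed Seed for the subsample.
#' @return A `smoothed_track`: data frame `pos`, `mean`, `lower95`,
#'   `upper95` plus attributes `hyperparams` (range, marginal_sd, noise_sd),
#'   `converged`, `genome_length`.
#' @export
fit_circular_smoother <- function(map, values, grid_step = NULL,
                                  max_points = 1000, hyper = NULL, seed = 1L) {
  L <- attr(map, "genome_length")
  if (is.null(L)) stopf("'map' must carry a genome_length attribute")
  pos <- map$position
  v <- if (!is.null(names(values))) values[map$gene_id] else values
  keep <- !is.na(v)
  pos <- pos[keep]; v <- as.numeric(v[keep])
  if (length(v) < 10L) stopf("need at least 10 mapped genes with values")
  if (length(v) > max_points) {
    idx <- with_seed(seed, sample.int(length(v), max_points))
    pos <- pos[idx]; v <- v[idx]
  }
  n <- length(v)
  m <- mean(v)
  yc <- v - m
  Dcor_fun <- local({
    d0 <- abs(outer(pos, pos, "-"))
    dc <- pmin(d0, L - d0)
    function(rho) matern32(dc, rho)
  })

  converged <- TRUE
  if (is.null(hyper)) {
    lb <- c(log(L / 500), log(1e-3)); ub <- c(log(L / 2), log(1e3))
    opt <- try(stats::optim(c(log(L / 20), log(0.5)), gp_profile_nll,
                            Dcor_fun = Dcor_fun, yc = yc, n = n,
                            method = "L-BFGS-B", lower = lb, upper = ub,
                            control = list(maxit = 100)),
               silent = TRUE)
    if (inherits(opt, "try-error") || !is.finite(opt$value) ||
        opt$value >= 1e10) {
      converged <- FALSE
      f1 <- function(lt) gp_profile_nll(c(log(L / 20), lt), Dcor_fun, yc, n)
      lt <- stats::optimize(f1, c(log(1e-3), log(1e3)))$minimum
      lpar <- c(log(L / 20), lt)
    } else lpar <- opt$par
    rho <- exp(lpar[1]); tau <- exp(lpar[2])
  } else {
    rho <- hyper$range; tau <- hyper$noise_ratio
  }

  Ct <- Dcor_fun(rho)
  diag(Ct) <- diag(Ct) + tau^2 + 1e-8
  ch <- chol_jitter(Ct)
  if (is.null(ch)) stopf("covariance factorization failed")
  a <- backsolve(ch, backsolve(ch, yc, transpose = TRUE))
  s2 <- sum(yc * a) / n                      # profiled marginal variance

  grid_step <- grid_step %||% (L / 2000)
  grid <- seq(0, L, by = grid_step)
  if (grid[length(grid)] < L) grid <- c(grid, L)
  Ks <- circ_corr(grid, pos, L, rho)
  mu <- m + as.numeric(Ks %*% a)
  B <- backsolve(ch, t(Ks), transpose = TRUE)  # solves t(ch) %*% B = t(Ks)
  varf <- pmax(s2 * (1 - colSums(B^2)), 0)
  band <- 1.96 * sqrt(varf)

  out <- data.frame(pos = grid, mean = mu,
                    lower95 = mu - band, upper95 = mu + band)
  structure(out,
            hyperparams = list(range = rho, marginal_sd = sqrt(s2),
                               noise_sd = tau * sqrt(s2)),
            converged = converged, genome_length = L,
            class = c("smoothed_track", "data.frame"))
}

#' @export
print.smoothed_track <- function(x, ...) {
  h <- attr(x, "hyperparams")
  cat(sprintf(paste0("smoothed_track: %d grid points on a %.0f bp circle\n",
                     "  range = %.0f bp, marginal_sd = %.3f, noise_sd = %.3f%s\n"),
              nrow(x), attr(x, "genome_length"), h$range, h$marginal_sd,
              h$noise_sd,
              if (isTRUE(attr(x, "converged"))) "" else " (fixed-range fallback)"))
  invisible(x)
}

#' @export
plot.smoothed_track <- function(x, ylab = "smoothed value", ...) {
  graphics::plot(x$pos, x$mean, type = "n", xlab = "genome position (bp)",
                 ylab = ylab, ylim = range(x$lower95, x$upper95), ...)
  graphics::polygon(c(x$pos, rev(x$pos)), c(x$lower95, rev(x$upper95)),
                    col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  graphics::lines(x$pos, x$mean, col = "steelblue4", lwd = 2)
  invisible(x)
}

#' Detect retention hotspots on a smoothed track
#'
#' Retention regions are where the smoothed statistic shrinks towards zero
#' relative to the track-wide predominant level (the median of the
#' posterior mean), regardless of the predominant sign. A grid cell is
#' "hot" when `|mean| < |reference| * threshold_fraction` and the credible
#' band excludes the reference level. Maximal runs of hot cells become
#' intervals; a run spanning the origin is returned as one wrapped interval
#' (`wraps = TRUE`, `start > end`).
#'
#' @param track A `smoothed_track`.
#' @param threshold_fraction Shrinkage fraction of the reference magnitude.
#' @param reference_level Optional override of the reference (default the
#'   median of the track mean).
#' @return Data frame `start`, `end`, `wraps` (possibly empty).
#' @export
detect_retention_hotspots <- function(track, threshold_fraction = 0.5,
                                      reference_level = NULL) {
  stopifnot(inherits(track, "smoothed_track"))
  L <- attr(track, "genome_length")
  # drop the duplicated periodic endpoint
  tr <- track[track$pos < L, , drop = FALSE]
  ref <- reference_level %||% stats::median(tr$mean)
  hot <- abs(tr$mean) < abs(ref) * threshold_fraction &
    (ref < tr$lower95 | ref > tr$upper95)
  if (!any(hot)) {
    return(data.frame(start = numeric(), end = numeric(), wraps = logical()))
  }
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(i1 = starts[r$values], i2 = ends[r$values])
  step <- tr$pos[2] - tr$pos[1]
  iv <- data.frame(start = tr$pos[runs$i1], end = tr$pos[runs$i2] + step,
                   wraps = FALSE)
  # merge a run touching the end of the circle with one starting at 0
  if (nrow(iv) > 1 && iv$start[1] == 0 && abs(iv$end[nrow(iv)] - L) < step / 2) {
    iv$start[1] <- iv$start[nrow(iv)]
    iv$wraps[1] <- TRUE
    iv <- iv[-nrow(iv), , drop = FALSE]
  } else if (nrow(iv) == 1 && iv$start[1] == 0 && abs(iv$end[1] - L) < step / 2) {
    # the whole circle is hot; keep as a single full interval
    iv$end[1] <- L
  }
  rownames(iv) <- NULL
  iv
}

#' Circular kernel density track of core-gene positions
#'
#' Wrapped-Gaussian kernel density of core-gene positions on the circle,
#' scaled so the density integrates to the core-gene count over one full
#' turn.
#'
#' @param map A `genome_map`.
#' @param bandwidth Kernel SD in bp.
#' @param grid_step Grid spacing in bp.
#' @return A `smoothed_track` (band equal to the mean: the KDE carries no
#'   uncertainty).
#' @export
core_density_track <- function(map, bandwidth = 50000, grid_step = NULL) {
  L <- attr(map, "genome_length")
  p <- map$position[map$label == "core"]
  if (!length(p)) stopf("need at least one core gene")
  grid_step <- grid_step %||% (L / 2000)
  grid <- seq(0, L, by = grid_step)
  if (grid[length(grid)] < L) grid <- c(grid, L)
  dens <- rep(0, length(grid))
  for (j in -3:3) {
    dens <- dens + colSums(matrix(
      stats::dnorm(outer(p + j * L, grid, function(a, b) a - b), sd = bandwidth),
      nrow = length(p)))
  }
  structure(data.frame(pos = grid, mean = dens, lower95 = dens,
                       upper95 = dens),
            hyperparams = list(range = bandwidth, marginal_sd = NA_real_,
                               noise_sd = 0),
            converged = TRUE, genome_length = L,
            class = c("smoothed_track", "data.frame"))
}

# Jaccard of two logical vectors over grid cells.
grid_jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

hotspot_cells <- function(intervals, grid, L) {
  hot <- rep(FALSE, length(grid))
  for (i in seq_len(nrow(intervals))) {
    s <- intervals$start[i]; e <- intervals$end[i]
    hot <- hot | if (isTRUE(intervals$wraps[i]) || s > e) {
      grid >= s | grid < e
    } else grid >= s & grid < e
  }
  hot
}

#' Test co-location of retention hotspots with core-gene density
#'
#' Computes the Jaccard overlap (on the prediction grid) between retention
#' hotspot intervals and the top-decile core-density region, and compares
#' it with a permutation null in which core-gene positions are redrawn
#' uniformly on the circle.
#'
#' @param hotspots Intervals from [detect_retention_hotspots()].
#' @param map A `genome_map`.
#' @param bandwidth Core-density kernel SD in bp.
#' @param top_quantile Density quantile defining "high core density".
#' @param n_perm Number of position shuffles.
#' @param seed Integer seed.
#' @return List: `jaccard`, `p`, `null` (permutation Jaccards).
#' @export
core_colocation_test <- function(hotspots, map, bandwidth = 50000,
                                 top_quantile = 0.9, n_perm = 99, seed = 1L) {
  L <- attr(map, "genome_length")
  ct <- core_density_track(map, bandwidth)
  grid <- ct$pos[ct$pos < L]
  dens <- ct$mean[ct$pos < L]
  hs <- hotspot_cells(hotspots, grid, L)
  top <- dens >= stats::quantile(dens, top_quantile)
  obs <- grid_jaccard(hs, top)
  n_core <- sum(map$label == "core")
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(r) {
      p <- stats::runif(n_core, 0, L)
      d <- rep(0, length(grid))
      for (j in -3:3) {
        d <- d + colSums(matrix(
          stats::dnorm(outer(p + j * L, grid, function(a, b) a - b),
                       sd = bandwidth), nrow = n_core))
      }
      grid_jaccard(hs, d >= stats::quantile(d, top_quantile))
    }, numeric(1))
  })
  list(jaccard = obs, p = (1 + sum(null >= obs)) / (n_perm + 1), null = null)
}
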