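# Environmental binning of soil samples, pairwise Hudson-style Fst between
# soil-sample populations of haploid strains, and permutation inference for
# the Fst ~ stress regression.

#' Bin soil samples by position in stress space
#'
#' Ward hierarchical clustering on Euclidean distance in the 4-D stress
#' space, cut to `k` clusters, followed by greedy rebalancing (boundary
#' samples moved to their nearest under-full cluster) until bin sizes differ
#' by at most one. The within-bin vs between-bin mean distance ratio is
#' attached as an attribute (values below 1 indicate bins more
#' environmentally homogeneous than the background).
#'
#' @param stress A `stress_profile` table.
#' @param k Number of bins (default 5).
#' @return Named integer vector sample -> bin, with attribute
#'   `distance_ratio`.
#' @export
bin_samples_by_stress <- function(stress, k = 5L) {
  X <- stress_matrix(stress)
  n <- nrow(X)
  if (k > n) stopf("k = %d exceeds the number of samples (%d)", k, n)
  D <- as.matrix(stats::dist(X))
  cl <- stats::cutree(stats::hclust(stats::as.dist(D), method = "ward.D2"), k)

  lo <- floor(n / k); hi <- ceiling(n / k)
  repeat {
    sizes <- tabulate(cl, k)
    over <- which(sizes > hi)
    under <- which(sizes < lo)
    if (!length(over) && !length(under)) break
    # move the boundary sample of an over-full (or any donor) bin closest to
    # the centroid of an under-full bin
    recv <- if (length(under)) under else which(sizes < hi)
    don <- if (length(over)) over else which(sizes > lo)
    best <- NULL
    for (b in recv) {
      cen <- colMeans(X[cl == b, , drop = FALSE])
      cand <- which(cl %in% don)
      d2 <- colSums((t(X[cand, , drop = FALSE]) - cen)^2)
      i <- cand[which.min(d2)]
      if (is.null(best) || min(d2) < best$d) best <- list(i = i, b = b, d = min(d2))
    }
    cl[best$i] <- best$b
  }
  within <- D[outer(cl, cl, "==") & upper.tri(D)]
  between <- D[outer(cl, cl, "!=") & upper.tri(D)]
  structure(stats::setNames(cl, rownames(X)),
            distance_ratio = mean(within) / mean(between))
}

#' Within-bin soil-sample pairs
#'
#' @param bins Named bin assignment from [bin_samples_by_stress()].
#' @return Data frame `sample_a`, `sample_b`, `bin_id` with all unordered
#'   pairs of distinct samples sharing a bin.
#' @export
within_bin_pairs <- function(bins) {
  out <- lapply(sort(unique(bins)), function(b) {
    s <- sort(names(bins)[bins == b])
    if (length(s) < 2L) return(NULL)
    idx <- utils::combn(length(s), 2)
    data.frame(sample_a = s[idx[1, ]], sample_b = s[idx[2, ]], bin_id = b,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Per-sample per-locus allele statistics: list(n, p, hw) matrices.
sample_allele_stats <- function(genotypes, sample_of) {
  samples <- unique(unname(sample_of[rownames(genotypes)]))
  n <- p <- hw <- matrix(NA_real_, length(samples), ncol(genotypes),
                         dimnames = list(samples, NULL))
  for (j in seq_along(samples)) {
    G <- genotypes[sample_of[rownames(genotypes)] == samples[j], , drop = FALSE]
    nn <- colSums(!is.na(G))
    xx <- colSums(G == 1L, na.rm = TRUE)
    pp <- ifelse(nn > 0, xx / nn, NA_real_)
    n[j, ] <- nn; p[j, ] <- pp
    hw[j, ] <- ifelse(nn >= 2, 2 * pp * (1 - pp) * nn / (nn - 1), NA_real_)
  }
  list(n = n, p = p, hw = hw)
}

#' Pairwise Hudson-style Fst between soil-sample populations
#'
#' Haploid Hudson estimator per locus: within-population heterozygosity
#' `Hw = (2 p_a (1 - p_a) n_a / (n_a - 1) + 2 p_b (1 - p_b) n_b / (n_b - 1)) / 2`
#' (unbiased for finite samples), between-population heterozygosity
#' `Hb = p_a (1 - p_b) + p_b (1 - p_a)`, combined across loci as a ratio of
#' averages: `Fst = 1 - mean(Hw) / mean(Hb)`. Loci monomorphic for the same
#' allele in both populations are excluded; loci need at least two typed
#' strains in each population. Negative per-pair values are retained by
#' default (unbiased for the downstream regression).
#'
#' @param genotypes Strain x locus 0/1 matrix (NA = missing).
#' @param sample_of Named strain -> soil-sample map.
#' @param pairs Data frame `sample_a`, `sample_b` (e.g. from
#'   [within_bin_pairs()]).
#' @param truncate Truncate negative Fst at 0?
#' @return `pairs` with columns `fst` and `n_loci_used` appended; pairs with
#'   no usable loci get `NA` with a warning.
#' @export
pairwise_fst <- function(genotypes, sample_of, pairs, truncate = FALSE) {
  stats_ <- sample_allele_stats(genotypes, sample_of)
  miss <- setdiff(unique(c(pairs$sample_a, pairs$sample_b)),
                  rownames(stats_$p))
  if (length(miss)) stopf("sample(s) absent from the SNP matrix: %s",
                          paste(utils::head(miss, 5), collapse = ", "))
  fst <- nuse <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$sample_a[i]; b <- pairs$sample_b[i]
    pa <- stats_$p[a, ]; pb <- stats_$p[b, ]
    usable <- stats_$n[a, ] >= 2 & stats_$n[b, ] >= 2 &
      !(pa == pb & (pa == 0 | pa == 1))
    usable[is.na(usable)] <- FALSE
    if (!any(usable)) { fst[i] <- NA_real_; nuse[i] <- 0L; next }
    hw <- (stats_$hw[a, usable] + stats_$hw[b, usable]) / 2
    hb <- pa[usable] * (1 - pb[usable]) + pb[usable] * (1 - pa[usable])
    fst[i] <- 1 - mean(hw) / mean(hb)
    nuse[i] <- sum(usable)
  }
  if (truncate) fst <- pmax(fst, 0)
  if (anyNA(fst)) warnf("%d pair(s) had no usable loci; Fst undefined",
                        sum(is.na(fst)))
  pairs$fst <- fst
  pairs$n_loci_used <- as.integer(nuse)
  pairs
}

# t statistics of the 4 stress slopes for given pair covariates.
ols_t <- function(Xd, y) {
  qr_ <- qr(Xd)
  cf <- qr.coef(qr_, y)
  res <- y - Xd %*% cf
  df <- nrow(Xd) - ncol(Xd)
  s2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qr_))
  se <- sqrt(pmax(diag(XtXinv) * s2, 0))
  tt <- ifelse(se > 0, cf / se, 0)
  list(coef = cf[-1], t = tt[-1], se = se[-1])
}

#' Regression of pairwise Fst on mean stress with permutation inference
#'
#' OLS of within-bin pairwise Fst on the four mean-stress covariates (the
#' elementwise mean of the two samples' stress profiles). Because pairs
#' share soil samples, significance comes from a permutation test that
#' permutes whole stress profiles across soil samples (preserving stress
#' collinearity and the pair dependence structure), recomputing pair means
#' and slopes each time. Two-sided p-values use the add-one estimator
#' `(1 + #(|t*| >= |t|)) / (n_perm + 1)`.
#'
#' @param fst_pairs Output of [pairwise_fst()].
#' @param stress A `stress_profile` table.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return List: `slopes`, `t`, `se`, `p_perm` (named by stress),
#'   `mean_stress` (pair covariates), `n_pairs`, `n_perm`.
#' @export
fst_stress_regression <- function(fst_pairs, stress, n_perm = 999, seed = 1L) {
  keep <- !is.na(fst_pairs$fst)
  pairs <- fst_pairs[keep, , drop = FALSE]
  if (nrow(pairs) < 10L) stopf("need at least 10 Fst pairs (got %d)", nrow(pairs))
  X <- stress_matrix(stress)
  ia <- match(pairs$sample_a, rownames(X))
  ib <- match(pairs$sample_b, rownames(X))
  if (anyNA(ia) || anyNA(ib)) stopf("pair sample(s) missing from the stress table")
  y <- pairs$fst
  mk <- function(S) cbind(1, (S[ia, , drop = FALSE] + S[ib, , drop = FALSE]) / 2)
  Xd <- mk(X)
  if (qr(Xd)$rank < ncol(Xd)) stopf("degenerate design: collinear mean-stress covariates")
  obs <- ols_t(Xd, y)
  if (stats::var(y) == 0) {
    zero <- stats::setNames(rep(0, 4), STRESS_NAMES)
    return(list(slopes = zero, t = zero, se = stats::setNames(obs$se, STRESS_NAMES),
                p_perm = stats::setNames(rep(1, 4), STRESS_NAMES),
                mean_stress = Xd[, -1, drop = FALSE],
                n_pairs = nrow(pairs), n_perm = 0L))
  }
  exceed <- with_seed(seed, {
    ex <- rep(0L, 4)
    for (r in seq_len(n_perm)) {
      Sp <- X[sample.int(nrow(X)), , drop = FALSE]
      rownames(Sp) <- rownames(X)
      tp <- ols_t(mk(Sp), y)$t
      ex <- ex + (abs(tp) >= abs(obs$t))
    }
    ex
  })
  p <- (1 + exceed) / (n_perm + 1)
  ms <- Xd[, -1, drop = FALSE]
  colnames(ms) <- STRESS_NAMES
  list(slopes = stats::setNames(as.numeric(obs$coef), STRESS_NAMES),
       t = stats::setNames(as.numeric(obs$t), STRESS_NAMES),
       se = stats::setNames(as.numeric(obs$se), STRESS_NAMES),
       p_perm = stats::setNames(p, STRESS_NAMES),
       mean_stress = ms, n_pairs = nrow(pairs), n_perm = n_perm)
}
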