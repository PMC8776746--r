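# Second-stage regression of per-gene z-scores on functional traits,
# categorical effect tests, and environment-specific loss weighting with a
# tetrahedron embedding.

#' Regress gene z-scores on functional traits
#'
#' Ordinary least squares of the long-format z table on stress type (a
#' 4-level categorical predictor without a global intercept, so the four
#' per-stress mean z coefficients are reported directly) plus stress-by-
#' trait interactions for similarity, betweenness and duplication.
#' Heteroskedasticity-robust (sandwich) standard errors are used throughout
#' because per-gene z variances are heterogeneous.
#'
#' @param z_long Data frame with columns `gene_id`, `environment`
#'   (one of the four stresses) and `z`.
#' @param traits Data frame `gene_id`, `mean_cosine` (similarity),
#'   `betweenness`, `duplication`. Traits are standardized internally
#'   (mean 0, SD 1) so interaction coefficients are per-SD effects.
#' @param hc_type Sandwich estimator type (see [sandwich::vcovHC()]).
#' @return A `trait_regression` object: `main_effects` and `interactions`
#'   tables (estimate, robust SE, 95% CI, p), the underlying `lm` fit, the
#'   robust vcov, and the observed standardized trait ranges.
#' @export
fit_trait_regression <- function(z_long, traits, hc_type = "HC1") {
  need <- c("gene_id", "environment", "z")
  if (!all(need %in% names(z_long))) {
    stopf("'z_long' needs columns %s", paste(need, collapse = ", "))
  }
  ti <- match(z_long$gene_id, traits$gene_id)
  if (anyNA(ti)) stopf("trait values missing for some genes")
  zsc <- function(v, nm) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      stopf("trait '%s' is constant; the trait regression is rank deficient", nm)
    }
    (v - mean(v)) / s
  }
  df <- data.frame(
    z = z_long$z,
    environment = factor(z_long$environment, levels = STRESS_NAMES),
    similarity = zsc(traits$mean_cosine[ti], "similarity"),
    betweenness = zsc(traits$betweenness[ti], "betweenness"),
    duplication = zsc(traits$duplication[ti], "duplication"))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  fit <- stats::lm(z ~ 0 + environment +
                     environment:similarity + environment:betweenness +
                     environment:duplication, data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stopf("rank-deficient trait regression; collinear term(s): %s",
          paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  V <- sandwich::vcovHC(fit, type = hc_type)
  se <- sqrt(diag(V))
  tab <- data.frame(term = names(cf), estimate = unname(cf), se = unname(se),
                    lower95 = unname(cf - 1.96 * se),
                    upper95 = unname(cf + 1.96 * se),
                    p = 2 * stats::pnorm(-abs(unname(cf) / unname(se))),
                    stringsAsFactors = FALSE)
  is_int <- grepl(":", tab$term)
  inter <- tab[is_int, ]
  inter$environment <- sub("^environment([a-z]+):.*$", "\\1", inter$term)
  inter$trait <- sub("^.*:", "", inter$term)
  main <- tab[!is_int, ]
  main$environment <- sub("^environment", "", main$term)
  structure(list(main_effects = main, interactions = inter, fit = fit,
                 vcov = V,
                 trait_range = vapply(df[c("similarity", "betweenness",
                                           "duplication")], range, numeric(2))),
            class = "trait_regression")
}

#' @export
print.trait_regression <- function(x, ...) {
  cat("trait_regression: per-stress mean z (main effects)\n")
  print(x$main_effects[, c("environment", "estimate", "se", "p")],
        row.names = FALSE, digits = 3)
  cat("stress x trait interactions\n")
  print(x$interactions[, c("environment", "trait", "estimate", "se", "p")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Predict z-scores over a trait grid
#'
#' Linear predictor with 95% confidence band (robust vcov) for one trait
#' varied over a grid, the other traits held at 0 (their standardized mean).
#'
#' @param result A `trait_regression`.
#' @param trait One of `"similarity"`, `"betweenness"`, `"duplication"`.
#' @param values Grid of standardized trait values.
#' @param environments Stresses to predict for (default all four).
#' @return Data frame `environment`, `trait`, `value`, `predicted`,
#'   `lower95`, `upper95`. Warns when `values` extrapolate beyond the
#'   observed trait range.
#' @export
predict_z <- function(result, trait = "similarity",
                      values = seq(-2, 2, length.out = 41),
                      environments = STRESS_NAMES) {
  stopifnot(inherits(result, "trait_regression"))
  trait <- match.arg(trait, c("similarity", "betweenness", "duplication"))
  rng <- result$trait_range[, trait]
  if (any(values < rng[1] | values > rng[2])) {
    warnf("prediction grid extrapolates beyond the observed '%s' range", trait)
  }
  cf <- stats::coef(result$fit)
  out <- lapply(environments, function(e) {
    Xn <- matrix(0, length(values), length(cf),
                 dimnames = list(NULL, names(cf)))
    Xn[, paste0("environment", e)] <- 1
    Xn[, paste0("environment", e, ":", trait)] <- values
    est <- as.numeric(Xn %*% cf)
    se <- sqrt(rowSums((Xn %*% result$vcov) * Xn))
    data.frame(environment = e, trait = trait, value = values,
               predicted = est, lower95 = est - 1.96 * se,
               upper95 = est + 1.96 * se, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Test for z-score differences among functional categories
#'
#' One-way ANOVA of the per-gene z-scores by functional category (e.g. COG
#' class), run separately for each stress gradient.
#'
#' @param z_table Matrix or data frame of z columns `z_acidity`, ...,
#'   rows named by gene, or a `gene_stress_response` table.
#' @param categories Named character vector gene -> category.
#' @return Data frame `environment`, `F`, `df1`, `df2`, `p`.
#' @export
category_effect_test <- function(z_table, categories) {
  z <- if (inherits(z_table, "gene_stress_response")) z_matrix(z_table) else {
    m <- as.matrix(z_table)
    colnames(m) <- sub("^z_", "", colnames(m))
    m
  }
  cat_g <- categories[rownames(z)]
  keep <- !is.na(cat_g)
  z <- z[keep, , drop = FALSE]
  cat_g <- factor(cat_g[keep])
  if (nlevels(cat_g) < 2L) stopf("need at least 2 functional categories")
  if (any(table(cat_g) < 2L) || nrow(z) < 4L) {
    stopf("need at least 2 genes in every category")
  }
  do.call(rbind, lapply(STRESS_NAMES, function(e) {
    a <- stats::anova(stats::lm(z[, e] ~ cat_g))
    data.frame(environment = e, F = a$`F value`[1], df1 = a$Df[1],
               df2 = a$Df[2], p = a$`Pr(>F)`[1], stringsAsFactors = FALSE)
  }))
}

# Vertices of a unit regular tetrahedron, one per stress gradient.
TETRA_VERTICES <- matrix(c(1, 1, 1,
                           1, -1, -1,
                           -1, 1, -1,
                           -1, -1, 1) / sqrt(3),
                         nrow = 4, byrow = TRUE,
                         dimnames = list(c("acidity", "aridity", "heat",
                                           "salinity"), c("x", "y", "z")))

#' Barycentric loss weights and tetrahedron embedding
#'
#' For genes with a strong propensity to be lost (minimum z across
#' environments below `z_threshold`), distributes the loss signal over the
#' four stresses as rectified negative z-scores normalized to sum 1:
#' `w_e = max(-z_e, 0) / sum_f max(-z_f, 0)`. Each gene is embedded in a
#' regular tetrahedron whose vertices are the four stresses
#' (`xyz = sum_e w_e V_e`), and labelled with its dominant environment when
#' the maximum weight reaches `dominance`, else `"shared"`. The weight map
#' is invariant to positive rescaling of the z vector.
#'
#' @param responses A `gene_stress_response` table or z matrix.
#' @param z_threshold Inclusion cutoff on the minimum z (default -2).
#' @param dominance Minimum weight for an exclusive-environment label.
#' @return A `loss_weights` data frame: `gene_id`, `w_*` per stress, `x`,
#'   `y`, `z` tetrahedron coordinates, `dominant`.
#' @export
loss_weights <- function(responses, z_threshold = -2, dominance = 0.75) {
  z <- if (inherits(responses, "gene_stress_response")) {
    z_matrix(responses)
  } else {
    m <- as.matrix(responses)
    colnames(m) <- sub("^z_", "", colnames(m))
    m[, STRESS_NAMES, drop = FALSE]
  }
  keep <- apply(z, 1, min) < z_threshold
  z <- z[keep, , drop = FALSE]
  if (!nrow(z)) {
    out <- data.frame(gene_id = character(),
                      w_acidity = numeric(), w_aridity = numeric(),
                      w_heat = numeric(), w_salinity = numeric(),
                      x = numeric(), y = numeric(), z = numeric(),
                      dominant = character(), stringsAsFactors = FALSE)
    class(out) <- c("loss_weights", "data.frame")
    return(out)
  }
  rect <- pmax(-z, 0)
  tot <- rowSums(rect)
  stopifnot(all(tot > 0))  # guaranteed by the inclusion rule
  W <- rect / tot
  xyz <- W %*% TETRA_VERTICES
  wmax <- apply(W, 1, max)
  dom <- ifelse(wmax >= dominance, STRESS_NAMES[apply(W, 1, which.max)],
                "shared")
  out <- data.frame(gene_id = rownames(z),
                    w_acidity = W[, 1], w_aridity = W[, 2],
                    w_heat = W[, 3], w_salinity = W[, 4],
                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    dominant = dom, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("loss_weights", "data.frame")
  out
}

#' Counts of exclusively lost genes per environment
#'
#' Tallies genes whose loss weighting is dominated (weight at or above
#' `dominance`) by a single environment, and tests the four counts for
#' departure from uniformity with a chi-square test.
#'
#' @param lw A `loss_weights` table.
#' @param dominance Dominance threshold (recomputed from the weights).
#' @return List: `counts`, `proportions` (per stress plus `shared`),
#'   `chisq`, `df`, `p`.
#' @export
specificity_summary <- function(lw, dominance = 0.75) {
  W <- as.matrix(lw[, paste0("w_", STRESS_NAMES), drop = FALSE])
  if (!nrow(W)) {
    cnt <- stats::setNames(rep(0L, 5), c(STRESS_NAMES, "shared"))
    return(list(counts = cnt, proportions = cnt, chisq = NA_real_,
                df = NA_integer_, p = NA_real_))
  }
  wmax <- apply(W, 1, max)
  dom <- ifelse(wmax >= dominance, STRESS_NAMES[apply(W, 1, which.max)],
                "shared")
  cnt <- vapply(c(STRESS_NAMES, "shared"), function(k) sum(dom == k),
                integer(1))
  excl <- cnt[STRESS_NAMES]
  test <- if (sum(excl) > 0) stats::chisq.test(excl) else
    list(statistic = NA_real_, parameter = NA_integer_, p.value = NA_real_)
  list(counts = cnt, proportions = cnt / sum(cnt),
       chisq = unname(test$statistic), df = unname(test$parameter),
       p = test$p.value)
}
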