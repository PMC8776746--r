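# Downstream statistics on codon-level dN/dS summaries: stratified gene
# sampling by stress response, beta regression of purifying proportions,
# binomial modelling of positive-selection flags, and the population-level
# stress regression.
#
# The beta regression is fitted in-package by maximum likelihood (logit
# mean link, common precision phi) with an analytic gradient; proportions
# on the boundary are squeezed with (y (n - 1) + 0.5) / n before fitting.

#' Stratify genes into stress-response categories by z-score
#'
#' Pools: `decrease` when the minimum z across environments is below
#' `cut_lo`; `increase` when the maximum z exceeds `cut_hi` (and the gene is
#' not already in `decrease`); `none` when all |z| are below `neutral_band`.
#' A uniform random subsample of `n_per_cat` genes is drawn from each pool
#' (the whole pool, with a warning, when it is smaller). Pools are disjoint
#' and the draw is deterministic given `seed`.
#'
#' @param responses A `gene_stress_response` table (or z matrix).
#' @param n_per_cat Target genes per category.
#' @param cut_lo,cut_hi,neutral_band Category thresholds on z.
#' @param seed Integer seed for the subsample.
#' @return Data frame `gene_id`, `category` (`decrease`, `none`, `increase`).
#' @export
stratify_genes_by_z <- function(responses, n_per_cat = 1000,
                                cut_lo = -2, cut_hi = 2, neutral_band = 0.5,
                                seed = 1L) {
  z <- if (inherits(responses, "gene_stress_response")) {
    z_matrix(responses)
  } else as.matrix(responses)
  zmin <- apply(z, 1, min)
  zmax <- apply(z, 1, max)
  pools <- list(decrease = rownames(z)[zmin < cut_lo],
                increase = rownames(z)[zmax > cut_hi & zmin >= cut_lo],
                none = rownames(z)[pmax(abs(zmin), abs(zmax)) < neutral_band])
  empty <- names(pools)[lengths(pools) == 0L]
  if (length(empty)) stopf("empty stratification pool(s): %s",
                           paste(empty, collapse = ", "))
  with_seed(seed, {
    out <- lapply(names(pools), function(k) {
      ids <- pools[[k]]
      if (length(ids) < n_per_cat) {
        warnf("pool '%s' has only %d genes (target %d); taking all",
              k, length(ids), n_per_cat)
      } else {
        ids <- sample(ids, n_per_cat)
      }
      data.frame(gene_id = ids, category = k, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

# Beta log-likelihood with logit mean link; par = c(beta, log_phi).
beta_reg_nll <- function(par, y, X) {
  k <- ncol(X)
  mu <- stats::plogis(as.numeric(X %*% par[seq_len(k)]))
  phi <- exp(par[k + 1L])
  -sum(lgamma(phi) - lgamma(mu * phi) - lgamma((1 - mu) * phi) +
         (mu * phi - 1) * log(y) + ((1 - mu) * phi - 1) * log1p(-y))
}

beta_reg_grad <- function(par, y, X) {
  k <- ncol(X)
  eta <- as.numeric(X %*% par[seq_len(k)])
  mu <- stats::plogis(eta)
  phi <- exp(par[k + 1L])
  ystar <- log(y) - log1p(-y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  dldeta <- phi * (ystar - mustar) * mu * (1 - mu)
  dldphi <- digamma(phi) - mu * digamma(mu * phi) -
    (1 - mu) * digamma((1 - mu) * phi) + mu * log(y) + (1 - mu) * log1p(-y)
  -c(as.numeric(crossprod(X, dldeta)), phi * sum(dldphi))
}

#' Beta regression of proportions (logit link, common precision)
#'
#' Maximum-likelihood beta regression for responses in \[0, 1\].
#' Boundary-capable proportions are squeezed with `(y (n - 1) + 0.5) / n`
#' (n = number of observations) before fitting. The mean model is
#' `logit(mu) = X beta`; a single precision `phi` is estimated on the log
#' scale. Standard errors come from the inverse observed information.
#'
#' @param y Proportions in \[0, 1\].
#' @param X Covariate data frame (expanded via `model.matrix(~ .)`) or
#'   `NULL` for an intercept-only model.
#' @param squeeze Apply the boundary squeeze transform?
#' @return A `beta_regression` object: `coefficients`, `se`, `z`, `p`,
#'   `phi`, `loglik`, `vcov`, `converged`, `fitted`.
#' @export
fit_beta_regression <- function(y, X = NULL, squeeze = TRUE) {
  y <- as.numeric(y)
  if (anyNA(y) || any(y < 0 | y > 1)) stopf("'y' must be proportions in [0, 1]")
  n <- length(y)
  if (n < 3L) stopf("need at least 3 observations")
  if (squeeze) y <- (y * (n - 1) + 0.5) / n
  if (any(y <= 0 | y >= 1)) {
    stopf("boundary proportions present; use squeeze = TRUE")
  }
  Xm <- if (is.null(X)) matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")) else
    stats::model.matrix(~ ., data = as.data.frame(X))
  if (nrow(Xm) != n) stopf("'X' and 'y' lengths differ")

  beta0 <- stats::coef(stats::lm.fit(Xm, stats::qlogis(y)))
  mu0 <- mean(y)
  v0 <- max(stats::var(y), 1e-6)
  phi0 <- max(mu0 * (1 - mu0) / v0 - 1, 1)
  par0 <- c(beta0, log(phi0))

  opt <- stats::optim(par0, beta_reg_nll, beta_reg_grad, y = y, X = Xm,
                      method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  k <- ncol(Xm)
  V <- try(solve(opt$hessian), silent = TRUE)
  ok <- opt$convergence == 0 && !inherits(V, "try-error") &&
    all(is.finite(diag(V))) && all(diag(V) > 0)
  se <- if (ok) sqrt(diag(V)[seq_len(k)]) else rep(NA_real_, k)
  cf <- stats::setNames(opt$par[seq_len(k)], colnames(Xm))
  z <- cf / se
  structure(list(coefficients = cf, se = stats::setNames(se, colnames(Xm)),
                 z = z, p = 2 * stats::pnorm(-abs(z)),
                 phi = exp(opt$par[k + 1L]),
                 loglik = -opt$value,
                 vcov = if (ok) V[seq_len(k), seq_len(k), drop = FALSE] else NULL,
                 converged = ok,
                 fitted = stats::plogis(as.numeric(Xm %*% cf)),
                 y = y, X = Xm),
            class = "beta_regression")
}

#' @export
print.beta_regression <- function(x, ...) {
  cat(sprintf("beta_regression (logLik = %.2f, phi = %.2f%s)\n", x$loglik,
              x$phi, if (x$converged) "" else ", NOT converged"))
  print(round(cbind(estimate = x$coefficients, se = x$se, z = x$z, p = x$p), 4))
  invisible(x)
}

#' @export
logLik.beta_regression <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 1L,
            class = "logLik")
}

#' Binomial model of positive-selection flags by category
#'
#' Logistic regression of the any-codon-under-positive-selection flag on the
#' stress-response category, with per-category predicted proportions and
#' 95% intervals. Categories whose outcomes are all 0 or all 1 separate the
#' likelihood; they are flagged and their intervals replaced by exact
#' (Clopper-Pearson) binomial bounds.
#'
#' @param any_positive Logical (or 0/1) outcome per gene.
#' @param categories Factor or character category per gene.
#' @return List: `fit` (the glm), `contrasts` (coef table vs the reference
#'   category), `predicted` (category, n, proportion, lower95, upper95),
#'   `separated` (category names).
#' @export
fit_positive_selection_model <- function(any_positive, categories) {
  y <- as.integer(any_positive)
  cat_f <- factor(categories)
  if (nlevels(cat_f) < 2L) stopf("need at least 2 categories")
  rates <- tapply(y, cat_f, mean)
  separated <- names(rates)[rates %in% c(0, 1)]
  m <- suppressWarnings(stats::glm(y ~ cat_f, family = stats::binomial()))
  sm <- summary(m)$coefficients
  rownames(sm) <- sub("^cat_f", "", rownames(sm))
  pred <- do.call(rbind, lapply(levels(cat_f), function(k) {
    nk <- sum(cat_f == k); xk <- sum(y[cat_f == k])
    if (k %in% separated) {
      ci <- stats::binom.test(xk, nk)$conf.int
      data.frame(category = k, n = nk, proportion = xk / nk,
                 lower95 = ci[1], upper95 = ci[2], stringsAsFactors = FALSE)
    } else {
      nd <- data.frame(cat_f = factor(k, levels = levels(cat_f)))
      pr <- stats::predict(m, nd, type = "link", se.fit = TRUE)
      data.frame(category = k, n = nk, proportion = stats::plogis(pr$fit),
                 lower95 = stats::plogis(pr$fit - 1.96 * pr$se.fit),
                 upper95 = stats::plogis(pr$fit + 1.96 * pr$se.fit),
                 stringsAsFactors = FALSE)
    }
  }))
  list(fit = m, contrasts = sm, predicted = pred, separated = separated)
}

#' Population-level beta regression of purifying selection on stress
#'
#' Models the mean proportion of codons under credible purifying selection
#' per soil sample as a multiple beta regression on the sample's four
#' stress gradients.
#'
#' @param pop_summaries Data frame `sample_id`, `prop_purifying`.
#' @param stress A `stress_profile` table.
#' @return A `beta_regression` (slopes named by stress), or a flagged
#'   non-converged object when the response is degenerate (constant).
#' @export
population_dnds_model <- function(pop_summaries, stress) {
  need <- c("sample_id", "prop_purifying")
  if (!all(need %in% names(pop_summaries))) {
    stopf("'pop_summaries' needs columns %s", paste(need, collapse = ", "))
  }
  if (nrow(pop_summaries) < 10L) {
    stopf("need at least 10 soil samples for the population model (got %d)",
          nrow(pop_summaries))
  }
  X <- stress_matrix(stress)
  sx <- X[match(pop_summaries$sample_id, rownames(X)), , drop = FALSE]
  if (anyNA(sx)) stopf("sample(s) missing from the stress table")
  y <- pop_summaries$prop_purifying
  if (stats::var(y) == 0) {
    out <- structure(list(coefficients = stats::setNames(rep(NA_real_, 5),
                                                         c("(Intercept)", STRESS_NAMES)),
                          se = NULL, z = NULL, p = NULL, phi = Inf,
                          loglik = NA_real_, vcov = NULL, converged = FALSE,
                          status = "degenerate_constant_response"),
                     class = "beta_regression")
    return(out)
  }
  fit_beta_regression(y, as.data.frame(sx))
}
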