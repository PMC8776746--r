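# Hierarchical count models of gene richness / pangenome diversity and
# per-gene binomial occurrence models along the four stress gradients.
#
# All mixed models use the Laplace approximation with nested random
# intercepts (site, soil sample) via glmmTMB. The per-gene occurrence loop
# drives the compiled TMB objective directly (response swapped in place,
# tape rebuilt, nlminb restarted), which reproduces glmmTMB's estimates and
# standard errors at a fraction of the per-fit overhead.

#' Fit a negative-binomial mixed model of counts on the four stresses
#'
#' NB2 (mean/dispersion) regression of a count response on the four
#' standardized stress gradients entered simultaneously, with random
#' intercepts for site and/or soil sample. When no grouping factor has at
#' least two levels the model falls back to a fixed-effects fit
#' (`MASS::glm.nb`) and is flagged.
#'
#' Variance components are estimated by REML by default (less downward bias
#' with few grouping units, hence better-calibrated Wald tests), and
#' p-values use a t reference with between-within degrees of freedom: the
#' stress gradients vary at the soil-sample level, so df = (number of soil
#' samples) - (number of fixed effects). A normal reference with ML
#' variances is mildly anti-conservative at 60 samples.
#'
#' @param y Non-negative integer response (one value per observation).
#' @param stress_x Numeric matrix of the four stress covariates per
#'   observation (columns acidity, aridity, heat, salinity).
#' @param site,sample Grouping factors (either may be `NULL`).
#' @param reml Use REML for variance components?
#' @param fix_zero_re Fix all random-effect SDs at (numerically) zero; the
#'   fit then reduces to the fixed-effects model, which is the oracle
#'   equivalence used in the tests.
#' @return A `mixed_model_fit`: coefficients, standard errors, z, p-values,
#'   random-effect SDs, dispersion, log-likelihood, `converged`, `status`,
#'   `df` (t reference degrees of freedom).
#' @export
fit_count_glmm <- function(y, stress_x, site = NULL, sample = NULL,
                           reml = TRUE, fix_zero_re = FALSE) {
  if (anyNA(y) || any(y < 0) || any(y != round(y))) {
    stopf("'y' must be non-negative integers")
  }
  stress_x <- as.matrix(stress_x)
  if (ncol(stress_x) != 4L) stopf("'stress_x' must have the 4 stress columns")
  colnames(stress_x) <- STRESS_NAMES
  df <- data.frame(y = as.integer(y), stress_x)
  rand <- character()
  if (!is.null(site)) {
    df$site <- factor(site)
    if (nlevels(df$site) >= 2L) rand <- c(rand, "(1 | site)")
  }
  if (!is.null(sample)) {
    df$sample <- factor(sample)
    if (nlevels(df$sample) >= 2L) rand <- c(rand, "(1 | sample)")
  }
  fixed <- paste("y ~", paste(STRESS_NAMES, collapse = " + "))
  n_units <- if (!is.null(sample) && nlevels(factor(sample)) >= 2L) {
    nlevels(factor(sample))
  } else length(y)
  df_t <- max(n_units - 5L, 1L)

  if (length(rand)) {
    form <- stats::as.formula(paste(fixed, "+", paste(rand, collapse = " + ")))
    extra <- if (fix_zero_re) {
      nt <- length(rand)
      list(map = list(theta = factor(rep(NA, nt))),
           start = list(theta = rep(log(1e-6), nt)))
    } else list()
    m <- do.call(glmmTMB::glmmTMB,
                 c(list(form, data = df, family = glmmTMB::nbinom2(),
                        REML = reml), extra))
    sm <- summary(m)$coefficients$cond
    re_sd <- vapply(glmmTMB::VarCorr(m)$cond, function(v) attr(v, "stddev"),
                    numeric(1))
    conv <- isTRUE(m$fit$convergence == 0) && isTRUE(m$sdr$pdHess)
    out <- list(coefficients = sm[, "Estimate"],
                standard_errors = sm[, "Std. Error"],
                z = sm[, "z value"],
                p = 2 * stats::pt(-abs(sm[, "z value"]), df_t),
                random_effect_sds = re_sd,
                dispersion = stats::sigma(m),
                loglik = as.numeric(stats::logLik(m)),
                converged = conv, n_obs = nrow(df), df = df_t,
                status = if (conv) "ok" else "failed",
                model = m)
  } else {
    m <- MASS::glm.nb(stats::as.formula(fixed), data = df)
    sm <- summary(m)$coefficients
    out <- list(coefficients = sm[, "Estimate"],
                standard_errors = sm[, "Std. Error"],
                z = sm[, "z value"],
                p = 2 * stats::pt(-abs(sm[, "z value"]), df_t),
                random_effect_sds = c(site = 0, sample = 0),
                dispersion = m$theta,
                loglik = as.numeric(stats::logLik(m)),
                converged = m$converged, n_obs = nrow(df), df = df_t,
                status = "no_random_effects_fallback",
                model = m)
  }
  class(out) <- "mixed_model_fit"
  out
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat(sprintf("mixed_model_fit (%s, n = %d, logLik = %.2f)\n",
              x$status, x$n_obs, x$loglik))
  tab <- cbind(estimate = x$coefficients, se = x$standard_errors,
               z = x$z, p = x$p)
  print(round(tab, 4))
  if (length(x$random_effect_sds)) {
    cat("random-effect SDs:",
        paste(sprintf("%s = %.3f", names(x$random_effect_sds),
                      x$random_effect_sds), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.mixed_model_fit <- function(object, ...) object$coefficients

# Join per-observation stress covariates through the design table.
join_stress <- function(ids, id_col, design, stress) {
  X <- stress_matrix(stress)
  if (id_col == "sample_id") {
    sx <- X[match(ids, rownames(X)), , drop = FALSE]
    if (anyNA(sx)) stopf("observation(s) reference unknown soil samples")
    return(sx)
  }
  si <- match(ids, design$strain_id)
  if (anyNA(si)) stopf("strain(s) missing from the design table")
  sx <- X[match(design$sample_id[si], rownames(X)), , drop = FALSE]
  if (anyNA(sx)) stopf("design references soil samples absent from the stress table")
  sx
}

#' Fit the gene-richness model
#'
#' Negative-binomial mixed regression of per-strain gene richness on the
#' four stress gradients (entered simultaneously, accounting for
#' environmental collinearity), with site and soil sample random intercepts.
#'
#' @param richness Data frame from [gene_richness()].
#' @param stress A `stress_profile` table.
#' @param design Design table (strain_id, sample_id, site_id).
#' @return A `mixed_model_fit`.
#' @export
fit_richness_model <- function(richness, stress, design) {
  sx <- join_stress(richness$strain_id, "strain_id", design, stress)
  si <- match(richness$strain_id, design$strain_id)
  fit_count_glmm(richness$richness, sx,
                 site = design$site_id[si], sample = design$sample_id[si])
}

#' Fit the pangenome-diversity model
#'
#' Same count model as [fit_richness_model()] at the soil-sample level, with
#' a site random intercept only (soil sample is the observational unit).
#'
#' @param diversity Data frame from [pangenome_diversity()].
#' @param stress A `stress_profile` table.
#' @param design Design table.
#' @return A `mixed_model_fit`.
#' @export
fit_diversity_model <- function(diversity, stress, design) {
  sx <- join_stress(diversity$sample_id, "sample_id", design, stress)
  site <- design$site_id[match(diversity$sample_id, design$sample_id)]
  fit_count_glmm(diversity$diversity, sx, site = site, sample = NULL)
}

# Heuristics for a (quasi-)separated logistic fit.
looks_separated <- function(coefs, ses) {
  any(!is.finite(coefs)) || any(!is.finite(ses)) ||
    max(abs(coefs)) > 8 || max(ses) > 25
}

# Plain logistic fallback; returns list(coef, se, separated).
glm_occurrence_fit <- function(y, df) {
  df$y <- y  # override any template response present in df
  sep_warn <- FALSE
  m <- withCallingHandlers(
    stats::glm(y ~ acidity + aridity + heat + salinity,
               data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
      }
      invokeRestart("muffleWarning")
    })
  sm <- summary(m)$coefficients
  list(coef = sm[, 1], se = sm[, 2],
       separated = sep_warn && looks_separated(sm[, 1], sm[, 2]))
}

#' Fit binomial occurrence models for every gene
#'
#' For each (pre-filtered) gene, fits presence/absence across strains on the
#' four stress gradients with site and soil-sample random intercepts
#' (binomial GLMM, logit link, Laplace approximation) and extracts the
#' z-score (coefficient / SE) per stress. Genes whose mixed fit fails or is
#' quasi-separated are refit without random effects and flagged
#' `no_random_effects_fallback`; fully separated genes are flagged
#' `separation` with undefined z.
#'
#' @param pm A filtered `pangenome_matrix` (no singletons / ubiquitous
#'   genes).
#' @param stress A `stress_profile` table.
#' @param design Design table (strain_id, sample_id, site_id).
#' @param genes Optional subset of gene ids to fit.
#' @param winsorize Optional bound; finite z values are clamped to
#'   `[-winsorize, +winsorize]`.
#' @param fix_zero_re Fix both random-effect SDs at (numerically) zero, so
#'   the per-gene fit reduces to a plain logistic regression (the oracle
#'   limit used in the tests).
#' @param progress Print a progress line every 500 genes?
#' @return A `gene_stress_response` data frame: `gene_id`, `beta_*`, `se_*`,
#'   `z_*` for the four stresses, and `status`.
#' @export
fit_gene_occurrence_models <- function(pm, stress, design, genes = NULL,
                                       winsorize = NULL, fix_zero_re = FALSE,
                                       progress = FALSE) {
  stopifnot(inherits(pm, "pangenome_matrix"))
  genes <- genes %||% pm$genes
  pres <- presence(pm)[, genes, drop = FALSE]
  sx <- join_stress(rownames(pres), "strain_id", design, stress)
  si <- match(rownames(pres), design$strain_id)
  df <- data.frame(sx,
                   site = factor(design$site_id[si]),
                   sample = factor(design$sample_id[si]))
  n <- nrow(df)

  # Template objective: deterministic balanced response, same design for all
  # genes. Individual genes only swap the response vector.
  df$y <- rep_len(c(0L, 1L), n)
  tmpl <- glmmTMB::glmmTMB(
    y ~ acidity + aridity + heat + salinity + (1 | site) + (1 | sample),
    data = df, family = stats::binomial(), doFit = TRUE)
  obj <- tmpl$obj
  npar <- length(tmpl$fit$par)         # 5 beta + 2 log-sd
  n_theta <- npar - 5L
  lower <- c(rep(-30, 5), rep(log(1e-3), n_theta))
  upper <- c(rep(30, 5), rep(log(10), n_theta))
  theta0 <- rep(log(1e-6), n_theta)
  # objective over beta only, grouping SDs pinned at ~0
  fn_fix <- function(b) obj$fn(c(b, theta0))
  gr_fix <- function(b) obj$gr(c(b, theta0))[1:5]

  res <- matrix(NA_real_, length(genes), 12,
                dimnames = list(genes, c(paste0("beta_", STRESS_NAMES),
                                         paste0("se_", STRESS_NAMES),
                                         paste0("z_", STRESS_NAMES))))
  status <- rep("ok", length(genes))

  for (i in seq_along(genes)) {
    y <- as.numeric(pres[, i])
    ybar <- mean(y)
    cf <- se <- rep(NA_real_, 5)
    ok <- FALSE
    if (ybar > 0 && ybar < 1) {
      start_b <- c(stats::qlogis(min(max(ybar, 0.02), 0.98)), rep(0, 4))
      obj$env$data$yobs <- y
      fit <- try({
        obj$retape()
        if (fix_zero_re) {
          stats::nlminb(start_b, fn_fix, gr_fix,
                        lower = lower[1:5], upper = upper[1:5],
                        control = list(iter.max = 200, eval.max = 300))
        } else {
          stats::nlminb(c(start_b, rep(log(0.25), n_theta)),
                        obj$fn, obj$gr, lower = lower, upper = upper,
                        control = list(iter.max = 200, eval.max = 300))
        }
      }, silent = TRUE)
      if (!inherits(fit, "try-error") && all(is.finite(fit$par))) {
        H <- try(if (fix_zero_re) stats::optimHess(fit$par, fn_fix, gr_fix)
                 else stats::optimHess(fit$par, obj$fn, obj$gr),
                 silent = TRUE)
        V <- if (!inherits(H, "try-error")) try(solve(H), silent = TRUE) else H
        if (!inherits(V, "try-error") && all(is.finite(diag(V)[1:5])) &&
            all(diag(V)[1:5] > 0)) {
          cf <- fit$par[1:5]
          se <- sqrt(diag(V)[1:5])
          ok <- !looks_separated(cf, se)
        }
      }
    }
    if (!ok) {
      if (ybar == 0 || ybar == 1) {
        status[i] <- "failed"   # no variation at all: nothing to estimate
        next
      }
      g <- glm_occurrence_fit(as.integer(y), df)
      if (g$separated) {
        status[i] <- "separation"
        next
      }
      status[i] <- "no_random_effects_fallback"
      cf <- g$coef; se <- g$se
    }
    res[i, 1:4] <- cf[2:5]
    res[i, 5:8] <- se[2:5]
    res[i, 9:12] <- cf[2:5] / se[2:5]
    if (progress && i %% 500 == 0) {
      message(sprintf("  occurrence models: %d / %d genes", i, length(genes)))
    }
  }
  if (!is.null(winsorize)) {
    zc <- 9:12
    res[, zc] <- pmin(pmax(res[, zc], -winsorize), winsorize)
  }
  out <- data.frame(gene_id = genes, res, status = status,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("gene_stress_response", "data.frame")
  out
}

#' Extract the z-score matrix from a gene stress-response table
#'
#' @param responses A `gene_stress_response` table.
#' @param statuses Statuses whose z values are considered defined.
#' @return Numeric matrix genes x 4 stresses (rows with defined z only).
#' @export
z_matrix <- function(responses,
                     statuses = c("ok", "no_random_effects_fallback")) {
  keep <- responses$status %in% statuses
  m <- as.matrix(responses[keep, paste0("z_", STRESS_NAMES), drop = FALSE])
  rownames(m) <- responses$gene_id[keep]
  colnames(m) <- STRESS_NAMES
  m[stats::complete.cases(m), , drop = FALSE]
}

#' Summarize per-gene z-scores by environment
#'
#' Per stress gradient: mean, SD and a one-sample t test of the gene
#' z-scores against zero, plus a smoothed kernel density estimate of the
#' z distribution.
#'
#' @param responses A `gene_stress_response` table.
#' @param statuses Statuses included in the summary.
#' @return List with `table` (environment, n, mean_z, sd_z, t, df, p) and
#'   `density` (per-environment [stats::density()] objects).
#' @export
summarize_z <- function(responses,
                        statuses = c("ok", "no_random_effects_fallback")) {
  z <- z_matrix(responses, statuses)
  if (nrow(z) < 2L) stopf("need at least 2 genes with defined z-scores")
  tab <- do.call(rbind, lapply(STRESS_NAMES, function(e) {
    tt <- stats::t.test(z[, e])
    data.frame(environment = e, n = nrow(z), mean_z = mean(z[, e]),
               sd_z = stats::sd(z[, e]), t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               stringsAsFactors = FALSE)
  }))
  dens <- lapply(stats::setNames(STRESS_NAMES, STRESS_NAMES),
                 function(e) stats::density(z[, e]))
  list(table = tab, density = dens)
}
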