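STRESSES <- c("acidity", "aridity", "heat", "salinity")

# Wrap a z matrix (se = 1) in the gene_stress_response shape.
make_responses <- function(z, status = "ok") {
  out <- data.frame(gene_id = rownames(z),
                    matrix(z, nrow(z), 4,
                           dimnames = list(NULL, paste0("beta_", STRESSES))),
                    matrix(1, nrow(z), 4,
                           dimnames = list(NULL, paste0("se_", STRESSES))),
                    matrix(z, nrow(z), 4,
                           dimnames = list(NULL, paste0("z_", STRESSES))),
                    status = status, stringsAsFactors = FALSE)
  class(out) <- c("gene_stress_response", "data.frame")
  out
}

sim_presence <- function(design, stress, beta, alpha = 0, site_sd = 0,
                         sample_sd = 0, seed = 1) {
  set.seed(seed)
  X <- stresspan:::stress_matrix(stress)
  xs <- X[match(design$sample_id, rownames(X)), , drop = FALSE]
  sf <- factor(design$site_id); pf <- factor(design$sample_id)
  u <- rnorm(nlevels(sf), 0, site_sd)[as.integer(sf)] +
    rnorm(nlevels(pf), 0, sample_sd)[as.integer(pf)]
  p <- plogis(alpha + as.numeric(xs %*% beta) + u)
  rbinom(length(p), 1, p)
}

as_pm <- function(pres_mat, design) {
  dimnames(pres_mat) <- list(design$strain_id,
                             sprintf("g%03d", seq_len(ncol(pres_mat))))
  classify_genes(pangenome_matrix(pres_mat))
}

test_that("count GLMM with variance fixed at zero equals the plain NB fit", {
  design <- make_design(10, 3, 6)
  stress <- make_stress(design, seed = 101)
  X <- stresspan:::stress_matrix(stress)
  xs <- X[match(design$sample_id, rownames(X)), ]
  set.seed(101)
  y <- rnbinom(nrow(design), mu = exp(5 - 0.2 * xs[, "salinity"]), size = 20)
  si <- match(design$strain_id, design$strain_id)
  fit <- fit_count_glmm(y, xs, site = design$site_id, sample = design$sample_id,
                        reml = FALSE, fix_zero_re = TRUE)
  oracle <- MASS::glm.nb(y ~ acidity + aridity + heat + salinity,
                         data = data.frame(y = y, xs))
  expect_equal(unname(fit$coefficients), unname(coef(oracle)),
               tolerance = 1e-4)
})

test_that("degenerate grouping falls back to a flagged fixed-effects fit", {
  design <- make_design(1, 1, 30)
  stress <- data.frame(sample_id = unique(design$sample_id),
                       acidity = 0, aridity = 0, heat = 0, salinity = 0)
  set.seed(102)
  y <- rnbinom(30, mu = 50, size = 10)
  xs <- matrix(rnorm(120), 30, 4,
               dimnames = list(NULL, STRESSES))
  fit <- fit_count_glmm(y, xs, site = design$site_id, sample = design$sample_id)
  expect_equal(fit$status, "no_random_effects_fallback")
  expect_true(all(fit$random_effect_sds == 0))
})

test_that("richness model recovers planted slope signs at study scale", {
  design <- make_design(20, 3, 6)
  stress <- make_stress(design, seed = 103)
  X <- stresspan:::stress_matrix(stress)
  xs <- X[match(design$sample_id, rownames(X)), ]
  slopes <- c(-0.05, -0.07, -0.05, -0.10)
  hits <- 0L
  for (r in 1:10) {
    set.seed(1000 + r)
    sf <- factor(design$site_id); pf <- factor(design$sample_id)
    eta <- 8.85 + as.numeric(xs %*% slopes) +
      rnorm(nlevels(sf), 0, 0.03)[as.integer(sf)] +
      rnorm(nlevels(pf), 0, 0.03)[as.integer(pf)]
    rich <- data.frame(strain_id = design$strain_id,
                       richness = rnbinom(nrow(design), mu = exp(eta), size = 60))
    fit <- fit_richness_model(rich, stress, design)
    if (all(fit$coefficients[STRESSES] < 0)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("an intercept-only truth is reproduced within 2%", {
  design <- make_design(21, 3, 6)[1:374, ]  # trim to 374 strains
  stress <- make_stress(design, seed = 104)
  set.seed(104)
  rich <- data.frame(strain_id = design$strain_id,
                     richness = rnbinom(374, mu = 7000, size = 50))
  fit <- fit_richness_model(rich, stress, design)
  expect_lt(abs(exp(fit$coefficients[["(Intercept)"]]) - 7000) / 7000, 0.02)
})

test_that("diversity model uses the site random effect and recovers signs", {
  design <- make_design(20, 3, 6)
  stress <- make_stress(design, seed = 105)
  X <- stresspan:::stress_matrix(stress)
  hits <- 0L
  for (r in 1:10) {
    set.seed(2000 + r)
    sf <- factor(sub("_s.$", "", rownames(X)))
    eta <- 9 + as.numeric(X %*% c(-0.1, -0.1, -0.1, -0.15)) +
      rnorm(nlevels(sf), 0, 0.05)[as.integer(sf)]
    div <- data.frame(sample_id = rownames(X),
                      diversity = rnbinom(nrow(X), mu = exp(eta), size = 80))
    fit <- fit_diversity_model(div, stress, design)
    expect_false("sample" %in% names(fit$random_effect_sds))
    if (all(fit$coefficients[STRESSES] < 0)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("per-gene z-scores match a plain logistic oracle when REs are absent", {
  design <- make_design(20, 3, 6)
  stress <- make_stress(design, seed = 106)
  set.seed(106)
  n_genes <- 25
  betas <- matrix(rnorm(n_genes * 4, 0, 0.8), n_genes, 4)
  pres <- sapply(seq_len(n_genes), function(g) {
    sim_presence(design, stress, betas[g, ], seed = 3000 + g)
  })
  pm <- as_pm(pres, design)
  resp <- fit_gene_occurrence_models(pm, stress, design, fix_zero_re = TRUE)
  X <- stresspan:::stress_matrix(stress)
  xs <- data.frame(X[match(design$sample_id, rownames(X)), ])
  for (g in which(resp$status == "ok")) {
    o <- glm(pres[, g] ~ acidity + aridity + heat + salinity,
             data = xs, family = binomial())
    zo <- summary(o)$coefficients[-1, 3]
    zg <- unlist(resp[g, paste0("z_", STRESSES)])
    expect_lt(max(abs(zg - zo)), 0.05)
  }
})

test_that("planted strong slopes give the right z sign; separation is flagged", {
  design <- make_design(20, 3, 6)
  stress <- make_stress(design, seed = 107)
  n_genes <- 40
  pres <- sapply(seq_len(n_genes), function(g) {
    sim_presence(design, stress, c(0, 0, 0, -2), site_sd = 0.3,
                 sample_sd = 0.3, seed = 4000 + g)
  })
  # last gene: perfect separation on the salinity gradient
  X <- stresspan:::stress_matrix(stress)
  xs <- X[match(design$sample_id, rownames(X)), ]
  pres <- cbind(pres, as.integer(xs[, "salinity"] < 0))
  pm <- as_pm(pres, design)
  resp <- fit_gene_occurrence_models(pm, stress, design)
  expect_equal(resp$status[n_genes + 1], "separation")
  expect_true(all(is.na(resp$z_salinity[n_genes + 1])))
  ok <- resp$status[1:n_genes] %in% c("ok", "no_random_effects_fallback")
  expect_gte(mean(resp$z_salinity[1:n_genes][ok] < 0), 0.95)
})

test_that("doubling a planted |beta| does not decrease the median |z|", {
  design <- make_design(20, 3, 6)
  stress <- make_stress(design, seed = 108)
  z_med <- sapply(c(0.5, 1, 2), function(b) {
    pres <- sapply(1:15, function(g) {
      sim_presence(design, stress, c(0, 0, -b, 0), site_sd = 0.2,
                   sample_sd = 0.2, seed = round(5000 + 100 * b) + g)
    })
    resp <- fit_gene_occurrence_models(as_pm(pres, design), stress, design)
    median(abs(resp$z_heat), na.rm = TRUE)
  })
  expect_true(all(diff(z_med) > -1e-9))
})

test_that("z summaries detect planted shifts and reject single genes", {
  set.seed(109)
  z_sym <- make_z(lapply(1:400, function(i) rnorm(4)))
  s <- summarize_z(make_responses(z_sym))
  expect_lt(max(abs(s$table$mean_z)), 0.2)
  expect_named(s$density, STRESSES)

  z_neg <- make_z(lapply(1:400, function(i) rnorm(4, -0.5)))
  s2 <- summarize_z(make_responses(z_neg))
  expect_true(all(s2$table$mean_z < 0))
  expect_true(all(s2$table$p < 0.05))

  expect_error(summarize_z(make_responses(make_z(list(c(1, 1, 1, 1))))),
               "at least 2")
})

test_that("winsorization clamps extreme z-scores", {
  design <- make_design(6, 2, 5)
  stress <- make_stress(design, seed = 110)
  set.seed(110)
  pres <- sapply(1:5, function(g) rbinom(nrow(design), 1, 0.5))
  resp <- fit_gene_occurrence_models(as_pm(pres, design), stress, design,
                                     winsorize = 0.1)
  z <- z_matrix(resp)
  expect_lte(max(abs(z)), 0.1)
})
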