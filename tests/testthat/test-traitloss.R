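STRESSES <- c("acidity", "aridity", "heat", "salinity")

# Simulate a long-format z table with planted trait interactions.
sim_z_long <- function(n_genes, sim_eff, bet_eff, main = -1, noise = 1,
                       seed = 1) {
  set.seed(seed)
  traits <- data.frame(gene_id = sprintf("g%05d", seq_len(n_genes)),
                       mean_cosine = rnorm(n_genes),
                       betweenness = rnorm(n_genes),
                       duplication = rnorm(n_genes))
  z_long <- do.call(rbind, lapply(STRESSES, function(e) {
    data.frame(gene_id = traits$gene_id, environment = e,
               z = main + sim_eff * traits$mean_cosine +
                 bet_eff * traits$betweenness + rnorm(n_genes, 0, noise),
               stringsAsFactors = FALSE)
  }))
  list(z_long = z_long, traits = traits)
}

test_that("trait regression recovers planted interaction signs", {
  hits <- 0L
  for (r in 1:20) {
    d <- sim_z_long(2000, sim_eff = -0.5, bet_eff = +0.5, seed = r)
    fit <- fit_trait_regression(d$z_long, d$traits)
    sim_i <- fit$interactions[fit$interactions$trait == "similarity", ]
    bet_i <- fit$interactions[fit$interactions$trait == "betweenness", ]
    if (all(sim_i$estimate < 0) && all(bet_i$estimate > 0)) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("null trait interactions are covered by their CIs at ~95%", {
  cover <- integer(0)
  for (r in 1:25) {
    d <- sim_z_long(500, sim_eff = 0, bet_eff = 0, seed = 100 + r)
    fit <- fit_trait_regression(d$z_long, d$traits)
    ii <- fit$interactions
    cover <- c(cover, ii$lower95 <= 0 & ii$upper95 >= 0)
  }
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.99)
})

test_that("constant traits raise a rank-deficiency error", {
  d <- sim_z_long(50, 0, 0, seed = 5)
  d$traits$duplication <- 1
  expect_error(fit_trait_regression(d$z_long, d$traits), "constant|rank")
})

test_that("predictions reproduce main effects, slopes, and a design-matrix oracle", {
  d <- sim_z_long(800, sim_eff = -0.5, bet_eff = 0.3, seed = 9)
  fit <- fit_trait_regression(d$z_long, d$traits)
  pr0 <- predict_z(fit, "similarity", values = 0)
  main <- fit$main_effects
  expect_equal(pr0$predicted,
               main$estimate[match(pr0$environment, main$environment)],
               tolerance = 1e-12)
  # slope of prediction in the trait equals the interaction coefficient
  pr <- predict_z(fit, "similarity", values = c(0, 1))
  for (e in STRESSES) {
    sl <- diff(pr$predicted[pr$environment == e])
    ii <- fit$interactions
    expect_equal(sl, ii$estimate[ii$environment == e & ii$trait == "similarity"],
                 tolerance = 1e-12)
  }
  # grid predictions equal the explicit design-matrix product
  vals <- seq(-1, 1, by = 0.5)
  pr <- predict_z(fit, "betweenness", values = vals, environments = "heat")
  cf <- coef(fit$fit)
  X <- matrix(0, length(vals), length(cf), dimnames = list(NULL, names(cf)))
  X[, "environmentheat"] <- 1
  X[, "environmentheat:betweenness"] <- vals
  expect_equal(pr$predicted, as.numeric(X %*% cf), tolerance = 1e-12)
  expect_warning(predict_z(fit, "similarity", values = 99), "extrapolates")
})

test_that("category ANOVA has calibrated p-values and power", {
  set.seed(42)
  null_p <- replicate(200, {
    z <- make_z(lapply(1:60, function(i) rnorm(4)))
    cats <- setNames(rep(c("A", "B", "C"), each = 20), rownames(z))
    category_effect_test(z, cats)$p[1]
  })
  expect_gt(mean(null_p < 0.05), 0.01)
  expect_lt(mean(null_p < 0.05), 0.10)

  set.seed(43)
  power <- replicate(50, {
    z <- make_z(lapply(1:1000, function(i) rnorm(4)))
    cats <- setNames(rep(c("A", "B"), each = 500), rownames(z))
    z[cats == "B", 1] <- z[cats == "B", 1] + 1   # one shifted category
    category_effect_test(z, cats)$p[1] < 0.05
  })
  expect_gte(mean(power), 0.9)

  z <- make_z(list(c(0, 0, 0, 0), c(1, 1, 1, 1)))
  expect_error(category_effect_test(z, setNames(c("A", "B"), rownames(z))),
               "at least 2 genes")
  expect_error(category_effect_test(z, setNames(c("A", "A"), rownames(z))),
               "at least 2 .*categories")
})

test_that("loss weights map z-vectors onto the stress tetrahedron", {
  z <- make_z(list(c(-4, 0, 1, 2),      # pure acidity loss
                   c(-3, -3, -3, -3),   # shared loss -> centroid
                   c(-3, -1, 0, 0)))    # acidity-aridity edge
  lw <- loss_weights(z)
  expect_equal(unname(unlist(lw[1, 2:5])), c(1, 0, 0, 0))
  expect_equal(unname(unlist(lw[2, 2:5])), rep(0.25, 4))
  expect_equal(unname(unlist(lw[3, 2:5])), c(0.75, 0.25, 0, 0))
  # vertex and centroid coordinates are exact
  V <- stresspan:::TETRA_VERTICES
  expect_equal(unname(unlist(lw[1, c("x", "y", "z")])), unname(V["acidity", ]))
  expect_equal(unname(unlist(lw[2, c("x", "y", "z")])), c(0, 0, 0))
  expect_equal(lw$dominant, c("acidity", "shared", "acidity"))
  # genes without strong loss are excluded
  z2 <- make_z(list(c(-1, 0, 0, 0)))
  expect_equal(nrow(loss_weights(z2)), 0L)
})

test_that("loss weights are invariant to positive rescaling of z", {
  set.seed(8)
  z <- make_z(lapply(1:30, function(i) rnorm(4, -2, 2)))
  lw1 <- loss_weights(z)
  lw3 <- loss_weights(z * 3)   # scaling keeps the same genes past threshold * 3
  shared <- intersect(lw1$gene_id, lw3$gene_id)
  i1 <- match(shared, lw1$gene_id); i3 <- match(shared, lw3$gene_id)
  expect_equal(as.matrix(lw1[i1, 2:5]), as.matrix(lw3[i3, 2:5]),
               tolerance = 1e-12)
})

test_that("the tetrahedron embedding is injective on weight vectors", {
  V <- stresspan:::TETRA_VERTICES
  # the affine map w -> w V restricted to the simplex is injective iff the
  # vertex differences are linearly independent
  M <- t(V[2:4, ]) - V[1, ]
  expect_equal(qr(M)$rank, 3L)
})

test_that("specificity summary flags a planted acidity/aridity excess", {
  set.seed(14)
  z <- rbind(make_z(lapply(1:60, function(i) c(-5, rnorm(3, 0, 0.3)))),
             do.call(rbind, lapply(1:10, function(i) rnorm(4, -2.5, 0.2))))
  colnames(z) <- STRESSES
  rownames(z) <- sprintf("g%03d", seq_len(nrow(z)))
  lw <- loss_weights(z)
  sp <- specificity_summary(lw)
  expect_equal(names(which.max(sp$counts[STRESSES])), "acidity")
  expect_lt(sp$p, 0.05)
  expect_equal(sum(sp$proportions), 1)
  # empty input gives zero counts
  sp0 <- specificity_summary(loss_weights(make_z(list(c(1, 1, 1, 1)))))
  expect_true(all(sp0$counts == 0))
})
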