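# Synthetic-data generator: emulates every input the pipeline consumes,
# with planted ground truth, so all downstream stages are testable offline.
#
# Design: a 20-site x 3-soil-sample x 6-strain hierarchy; logistic
# stress-dependent gene occurrence with trait-dependent slopes; Balding-
# Nichols population differentiation rising with heat and salinity; beta-
# distributed codon selection summaries by planted stress-response category;
# and a circular genome map with a planted retention/core hotspot.

#' Simulation configuration
#'
#' Bundles and validates every parameter of the synthetic-data generator.
#' Defaults reproduce the study design the package targets: 20 sites with 3
#' soil samples each and 6 strains per soil sample, 5,000 genes, and
#' population differentiation that increases with heat and salinity.
#'
#' @param n_sites,samples_per_site,strains_per_sample Sampling hierarchy.
#' @param n_genes Total genes (core + accessory).
#' @param core_fraction Fraction of genes that are core (present in every
#'   strain).
#' @param stress_correlation 4x4 correlation matrix of the latent
#'   environmental variables (order acidity, aridity, heat, salinity).
#' @param occurrence_intercept_range Range (logit scale) of per-gene
#'   occurrence intercepts.
#' @param trait_effect_map 3x4 matrix of signed effects (rows: similarity,
#'   betweenness, duplication; columns: the four stresses) linking
#'   standardized gene traits to per-stress occurrence slopes.
#' @param stress_main_effect Length-4 mean occurrence slope per stress
#'   (log-odds per SD stress); negative values plant overall gene loss.
#' @param beta_sd SD of gene-specific slope noise around the trait-implied
#'   slope.
#' @param null_gene_fraction Fraction of accessory genes with essentially no
#'   stress response (slopes ~ N(0, 0.1), no trait or mean effect),
#'   emulating the environmentally unstructured bulk of real accessory
#'   genomes.
#' @param site_sd,sample_sd Random-intercept SDs (logit scale).
#' @param salinity_zero_prob Point mass of exact zeroes in raw salinity.
#' @param duplication_mean Mean number of extra copies per carrying strain
#'   for accessory genes (Poisson rate of the copy-count excess).
#' @param n_snp_loci SNP loci for the core-genome matrix.
#' @param fst_base Baseline Balding-Nichols differentiation in (0, 1).
#' @param fst_stress_slope Logit-scale increase of differentiation per unit
#'   of mean heat/salinity stress.
#' @param genome_length Circular genome length in bp.
#' @param hotspot_interval Planted retention hotspot, `[start, end)` in bp.
#' @param hotspot_enrichment Density enrichment of core and stress-neutral
#'   genes inside the hotspot relative to outside.
#' @param n_codons_range Range of per-gene codon counts for selection
#'   summaries.
#' @param selection_means Named mean proportions of purifying codons for the
#'   planted `loss`, `neutral`, `gain` categories.
#' @param selection_phi Beta precision of the purifying proportions.
#' @param positive_rates Named probabilities that a gene in each category has
#'   any codon under credible positive selection.
#' @param seed Master seed; every generator draws from seeds derived from it.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_sites = 20L,
                              samples_per_site = 3L,
                              strains_per_sample = 6L,
                              n_genes = 5000L,
                              core_fraction = 0.05,
                              stress_correlation = default_stress_correlation(),
                              occurrence_intercept_range = c(-1, 1),
                              trait_effect_map = default_trait_effect_map(),
                              stress_main_effect = c(acidity = -0.3, aridity = -0.3,
                                                     heat = -0.3, salinity = -0.3),
                              beta_sd = 1,
                              null_gene_fraction = 0.4,
                              site_sd = 0.3,
                              sample_sd = 0.3,
                              salinity_zero_prob = 0.3,
                              duplication_mean = 0.4,
                              n_snp_loci = 2000L,
                              fst_base = 0.05,
                              fst_stress_slope = 0.5,
                              genome_length = 8e6,
                              hotspot_interval = c(0, 850000),
                              hotspot_enrichment = 5,
                              n_codons_range = c(100L, 600L),
                              selection_means = c(loss = 0.80, neutral = 0.60,
                                                  gain = 0.75),
                              selection_phi = 20,
                              positive_rates = c(loss = 0.15, neutral = 0.05,
                                                 gain = 0.05),
                              seed = 1L) {
  assert_count(n_sites, "n_sites")
  assert_count(samples_per_site, "samples_per_site")
  assert_count(strains_per_sample, "strains_per_sample")
  assert_count(n_genes, "n_genes")
  assert_count(n_snp_loci, "n_snp_loci")
  assert_prob(core_fraction, "core_fraction")
  assert_prob(fst_base, "fst_base")
  assert_prob(salinity_zero_prob, "salinity_zero_prob", open = FALSE)
  R <- as.matrix(stress_correlation)
  if (nrow(R) != 4L || ncol(R) != 4L || max(abs(R - t(R))) > 1e-12 ||
      any(abs(diag(R) - 1) > 1e-12) ||
      inherits(try(chol(R), silent = TRUE), "try-error")) {
    stopf("'stress_correlation' must be a symmetric positive-definite 4x4 correlation matrix")
  }
  tem <- as.matrix(trait_effect_map)
  if (nrow(tem) != 3L || ncol(tem) != 4L) {
    stopf("'trait_effect_map' must be 3 traits x 4 stresses")
  }
  rownames(tem) <- c("similarity", "betweenness", "duplication")
  colnames(tem) <- STRESS_NAMES
  if (genome_length <= 0) stopf("'genome_length' must be positive")
  if (length(hotspot_interval) != 2L || hotspot_interval[1] < 0 ||
      hotspot_interval[2] <= hotspot_interval[1] ||
      hotspot_interval[2] > genome_length) {
    stopf("'hotspot_interval' must be a [start, end) interval within [0, genome_length)")
  }
  cfg <- list(n_sites = as.integer(n_sites),
              samples_per_site = as.integer(samples_per_site),
              strains_per_sample = as.integer(strains_per_sample),
              n_genes = as.integer(n_genes),
              core_fraction = core_fraction,
              stress_correlation = R,
              occurrence_intercept_range = occurrence_intercept_range,
              trait_effect_map = tem,
              stress_main_effect = stats::setNames(stress_main_effect, STRESS_NAMES),
              beta_sd = beta_sd, null_gene_fraction = null_gene_fraction,
              site_sd = site_sd, sample_sd = sample_sd,
              salinity_zero_prob = salinity_zero_prob,
              duplication_mean = duplication_mean,
              n_snp_loci = as.integer(n_snp_loci),
              fst_base = fst_base, fst_stress_slope = fst_stress_slope,
              genome_length = genome_length,
              hotspot_interval = hotspot_interval,
              hotspot_enrichment = hotspot_enrichment,
              n_codons_range = as.integer(n_codons_range),
              selection_means = selection_means,
              selection_phi = selection_phi,
              positive_rates = positive_rates,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

#' Default stress correlation (moderate environmental collinearity)
#' @return 4x4 correlation matrix.
#' @export
default_stress_correlation <- function() {
  R <- matrix(0.25, 4, 4, dimnames = list(STRESS_NAMES, STRESS_NAMES))
  diag(R) <- 1
  R
}

#' Default trait effect map
#'
#' Functionally redundant genes (high similarity, high duplication) get
#' negative occurrence slopes (more likely lost under stress); high
#' betweenness "bridge" genes get positive slopes (retained).
#' @return 3x4 signed effect matrix.
#' @export
default_trait_effect_map <- function() {
  matrix(c(rep(-0.4, 4),   # similarity
           rep(+0.3, 4),   # betweenness
           rep(-0.4, 4)),  # duplication
         nrow = 3, byrow = TRUE,
         dimnames = list(c("similarity", "betweenness", "duplication"),
                         STRESS_NAMES))
}

#' Simulate the sampling design and raw environment table
#'
#' Builds the site / soil-sample / strain hierarchy and draws raw
#' environmental measurements per soil sample: a latent multivariate normal
#' with the configured correlation, mapped to temperature (degrees C),
#' rainfall (mm), pH, and salinity. Salinity is non-negative with a point
#' mass of exact zeroes (so the downstream `log(x + 0.01)` transform is
#' exercised), produced by thresholding its latent coordinate, which
#' preserves the rank correlation with the other variables.
#'
#' @param config A [simulation_config()].
#' @return List with `design` (strain_id, sample_id, site_id) and
#'   `environment` (sample_id, temperature, rainfall, pH, salinity).
#' @export
simulate_design <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  S <- config$n_sites; m <- config$samples_per_site; k <- config$strains_per_sample
  site_id <- sprintf("site%02d", seq_len(S))
  sample_id <- as.vector(t(outer(site_id, seq_len(m),
                                 function(s, j) paste0(s, "_s", j))))
  design <- data.frame(
    strain_id = sprintf("%s_i%02d", rep(sample_id, each = k), rep(seq_len(k), S * m)),
    sample_id = rep(sample_id, each = k),
    site_id = rep(rep(site_id, each = m), each = k),
    stringsAsFactors = FALSE)

  env <- with_seed(derive_seed(config$seed, 1L), {
    z <- MASS::mvrnorm(S * m, mu = rep(0, 4), Sigma = config$stress_correlation)
    if (is.null(dim(z))) z <- matrix(z, nrow = 1)
    u <- stats::pnorm(z[, 4])
    p0 <- config$salinity_zero_prob
    sal <- ifelse(u < p0, 0, stats::qexp(pmax((u - p0) / (1 - p0), 0), rate = 0.5))
    data.frame(sample_id = sample_id,
               temperature = 25 + 5 * z[, 3],
               rainfall = pmax(600 + 200 * z[, 2], 5),
               pH = 6.5 + 0.8 * z[, 1],
               salinity = sal,
               stringsAsFactors = FALSE)
  })
  list(design = design, environment = env)
}

#' Simulate a gene interaction network
#'
#' Grows an undirected simple graph by duplication-divergence (a new gene
#' copies a random anchor's neighbourhood, each edge retained independently)
#' plus occasional "bridge" genes wired to several random existing genes.
#' The scheme guarantees a spread of both cosine-similarity and betweenness
#' values (coefficient of variation above 0.2 for networks of 200+ genes).
#'
#' @param n_genes Number of vertices (>= 4).
#' @param retain_prob Probability each anchor edge is copied (1 = pure
#'   duplication).
#' @param parent_edge_prob Probability of an edge to the anchor itself.
#' @param bridge_prob Probability a new gene is a bridge instead of a
#'   duplicate.
#' @param gene_ids Optional vertex names (default `g00001`, ...).
#' @param seed Integer seed.
#' @return An igraph object with named vertices.
#' @export
simulate_network <- function(n_genes, retain_prob = 0.5,
                             parent_edge_prob = 0.3, bridge_prob = 0.05,
                             gene_ids = NULL, seed = 1L) {
  assert_count(n_genes, "n_genes", min = 4L)
  assert_prob(retain_prob, "retain_prob", open = FALSE)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%05d", seq_len(n_genes))
  if (length(gene_ids) != n_genes) stopf("'gene_ids' must have length n_genes")
  with_seed(seed, {
    nbr <- vector("list", n_genes)  # adjacency as integer sets
    nbr[[1]] <- 2L; nbr[[2]] <- 1L  # seed edge
    for (v in 3:n_genes) {
      if (stats::runif(1) < bridge_prob && v > 6L) {
        targets <- sample.int(v - 1L, min(v - 1L, max(2L, ceiling(log(v)))))
      } else {
        anchor <- sample.int(v - 1L, 1L)
        keep <- nbr[[anchor]][stats::runif(length(nbr[[anchor]])) < retain_prob]
        targets <- keep
        if (stats::runif(1) < parent_edge_prob) targets <- c(targets, anchor)
        if (!length(targets)) targets <- anchor  # avoid isolated vertices
      }
      targets <- unique(targets)
      nbr[[v]] <- targets
      for (w in targets) nbr[[w]] <- c(nbr[[w]], v)
    }
    from <- rep.int(seq_len(n_genes), lengths(nbr))
    to <- unlist(nbr)
    sel <- from < to
    el <- cbind(gene_ids[from[sel]], gene_ids[to[sel]])
    build_network(as.data.frame(el, stringsAsFactors = FALSE),
                  isolated_genes = gene_ids)
  })
}

#' Simulate the pangenome matrix with planted occurrence slopes
#'
#' Gene g is present in strain s with probability
#' `logistic(alpha_g + sum_e beta_ge x_e(sample(s)) + u_site + u_sample)`.
#' The slopes `beta_ge` are built from the trait effect map so that genes
#' with high (standardized) similarity or duplication receive negative
#' slopes and high-betweenness genes non-negative slopes, plus gene-specific
#' noise. Core genes are present in every strain. Copy counts of present
#' genes are `1 + Poisson(lambda_g)` with a gene-specific duplication rate.
#'
#' @param design Design table from [simulate_design()].
#' @param stress A `stress_profile` table for the soil samples.
#' @param network_traits Data frame `gene_id`, `betweenness`, `mean_cosine`
#'   covering every accessory gene.
#' @param config A [simulation_config()].
#' @return List with `matrix` (a labelled `pangenome_matrix`) and `truth`
#'   (list: `true_beta`, `alpha`, `dup_rate`, `planted_category`,
#'   `true_richness_slopes`, `functional_category`).
#' @export
simulate_pangenome <- function(design, stress, network_traits, config) {
  stopifnot(inherits(config, "simulation_config"))
  n_genes <- config$n_genes
  n_core <- max(1L, round(config$core_fraction * n_genes))
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  core_ids <- gene_ids[seq_len(n_core)]
  acc_ids <- setdiff(gene_ids, core_ids)

  ti <- match(acc_ids, network_traits$gene_id)
  if (anyNA(ti)) {
    stopf("missing network trait for gene(s): %s",
          paste(utils::head(acc_ids[is.na(ti)], 5), collapse = ", "))
  }
  X <- stress_matrix(stress)
  xs <- X[match(design$sample_id, rownames(X)), , drop = FALSE]
  if (anyNA(xs)) stopf("design references soil samples absent from the stress table")

  with_seed(derive_seed(config$seed, 2L), {
    na <- length(acc_ids)
    zscale <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
    sim_z <- zscale(network_traits$mean_cosine[ti])
    bet_z <- zscale(network_traits$betweenness[ti])
    dup_rate <- stats::rgamma(na, shape = 1, scale = config$duplication_mean)
    dup_z <- zscale(dup_rate)
    tem <- config$trait_effect_map
    beta <- matrix(rep(config$stress_main_effect, each = na), na, 4) +
      outer(sim_z, tem["similarity", ]) +
      outer(bet_z, tem["betweenness", ]) +
      outer(dup_z, tem["duplication", ]) +
      matrix(stats::rnorm(na * 4, 0, config$beta_sd), na, 4)
    nullg <- stats::runif(na) < (config$null_gene_fraction %||% 0)
    beta[nullg, ] <- stats::rnorm(sum(nullg) * 4, 0, 0.1)
    dimnames(beta) <- list(acc_ids, STRESS_NAMES)
    alpha <- stats::runif(na, config$occurrence_intercept_range[1],
                          config$occurrence_intercept_range[2])

    # gene-specific site and soil-sample intercepts (matching the per-gene
    # occurrence model, where grouping effects are estimated per gene; a
    # shared draw would act as an unmodelled gradient that biases every
    # gene's coefficients in the same direction)
    site_f <- factor(design$site_id)
    samp_f <- factor(design$sample_id)
    U <- matrix(stats::rnorm(nlevels(site_f) * na, 0, config$site_sd),
                nlevels(site_f), na)[as.integer(site_f), , drop = FALSE] +
      matrix(stats::rnorm(nlevels(samp_f) * na, 0, config$sample_sd),
             nlevels(samp_f), na)[as.integer(samp_f), , drop = FALSE]

    eta <- xs %*% t(beta) +                       # strains x accessory genes
      rep(1, nrow(xs)) %o% alpha + U
    pres <- matrix(stats::rbinom(length(eta), 1L, stats::plogis(eta)),
                   nrow(eta), ncol(eta))
    extra <- matrix(stats::rpois(length(pres), rep(dup_rate, each = nrow(pres))),
                    nrow(pres), ncol(pres))
    acc_counts <- pres * (1L + extra)

    core_extra <- matrix(stats::rpois(nrow(xs) * n_core, 0.05), nrow(xs), n_core)
    counts <- cbind(1L + core_extra, acc_counts)
    dimnames(counts) <- list(design$strain_id, c(core_ids, acc_ids))

    dom <- apply(beta, 1, function(b) b[which.max(abs(b))])
    planted <- ifelse(dom <= -1, "loss", ifelse(dom >= 1, "gain", "neutral"))
    functional_category <- stats::setNames(
      sample(LETTERS[1:10], n_genes, replace = TRUE), gene_ids)

    pm <- classify_genes(pangenome_matrix(counts))
    truth <- list(true_beta = beta, alpha = alpha,
                  dup_rate = stats::setNames(dup_rate, acc_ids),
                  planted_category = stats::setNames(planted, acc_ids),
                  true_richness_slopes = config$stress_main_effect,
                  functional_category = functional_category,
                  core_ids = core_ids)
    list(matrix = pm, truth = truth)
  })
}

#' Simulate a binary core-genome SNP matrix
#'
#' Per soil sample j, differentiation is
#' `F_j = logistic(logit(fst_base) + fst_stress_slope * (heat_j + salinity_j)/2)`.
#' Per locus, the sample allele frequency is Balding-Nichols distributed
#' around an ancestral frequency `p0 ~ U(0.1, 0.9)`:
#' `p_jl ~ Beta(p0 (1-F_j)/F_j, (1-p0)(1-F_j)/F_j)`; haploid strain genotypes
#' are Bernoulli draws from the sample frequency. In the `F -> 0` limit the
#' sample frequencies equal `p0` exactly.
#'
#' @param design Design table from [simulate_design()].
#' @param stress A `stress_profile` table.
#' @param config A [simulation_config()]; `fst_base`, `fst_stress_slope` and
#'   `n_snp_loci` can be overridden.
#' @param fst_base,fst_stress_slope,n_loci Optional overrides.
#' @return List with `genotypes` (strain x locus 0/1 matrix), `sample_of`
#'   (named strain -> sample map) and `truth` (per-sample F, ancestral p0).
#' @export
simulate_snp_data <- function(design, stress, config,
                              fst_base = config$fst_base,
                              fst_stress_slope = config$fst_stress_slope,
                              n_loci = config$n_snp_loci) {
  stopifnot(inherits(config, "simulation_config"))
  assert_count(n_loci, "n_loci")
  X <- stress_matrix(stress)
  samples <- rownames(X)
  Fj <- stats::plogis(stats::qlogis(fst_base) +
                        fst_stress_slope * (X[, "heat"] + X[, "salinity"]) / 2)
  with_seed(derive_seed(config$seed, 3L), {
    p0 <- stats::runif(n_loci, 0.1, 0.9)
    P <- matrix(NA_real_, length(samples), n_loci,
                dimnames = list(samples, NULL))
    for (j in seq_along(samples)) {
      f <- Fj[j]
      P[j, ] <- if (f < 1e-9) p0 else
        stats::rbeta(n_loci, p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
    }
    si <- match(design$sample_id, samples)
    G <- matrix(stats::rbinom(nrow(design) * n_loci, 1L, P[si, , drop = FALSE]),
                nrow(design), n_loci,
                dimnames = list(design$strain_id,
                                sprintf("snp%05d", seq_len(n_loci))))
    list(genotypes = G,
         sample_of = stats::setNames(design$sample_id, design$strain_id),
         truth = list(F_by_sample = stats::setNames(Fj, samples), p0 = p0))
  })
}

#' Simulate per-gene codon selection summaries
#'
#' Emulates the per-codon credibility summaries of an upstream dN/dS
#' analysis. Per gene: codon count uniform on the configured range; the
#' proportion of codons under credible purifying selection drawn from a beta
#' distribution whose mean depends on the planted stress-response category
#' (higher for `loss` and `gain` than `neutral`); the any-positive-selection
#' flag is Bernoulli with an elevated rate only for `loss` genes. Genes with
#' zero codons are excluded.
#'
#' @param categories Named character vector gene -> planted category
#'   (`loss`, `neutral`, `gain`).
#' @param config A [simulation_config()].
#' @param seed Optional seed override.
#' @return Data frame `gene_id`, `n_codons`, `prop_purifying`, `any_positive`.
#' @export
simulate_selection_summaries <- function(categories, config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(names(categories))) stopf("'categories' must be named by gene id")
  bad <- setdiff(unique(categories), names(config$selection_means))
  if (length(bad)) stopf("unknown category: %s", paste(bad, collapse = ", "))
  with_seed(seed %||% derive_seed(config$seed, 4L), {
    n <- length(categories)
    rng <- config$n_codons_range
    n_codons <- sample(seq(rng[1], rng[2]), n, replace = TRUE)
    mu <- config$selection_means[categories]
    phi <- config$selection_phi
    prop <- stats::rbeta(n, mu * phi, (1 - mu) * phi)
    pos <- stats::rbinom(n, 1L, config$positive_rates[categories]) == 1L
    out <- data.frame(gene_id = names(categories), n_codons = n_codons,
                      prop_purifying = prop, any_positive = pos,
                      stringsAsFactors = FALSE)
    out[out$n_codons > 0L, , drop = FALSE]
  })
}

#' Simulate soil-sample level purifying-selection summaries
#'
#' Mean proportion of purifying codons per soil sample (over a core-gene
#' subsample), drawn from a beta distribution whose logit mean declines with
#' the configured stresses — by default heat and salinity only, planting the
#' "decreasing efficiency of selection" pattern.
#'
#' @param stress A `stress_profile` table.
#' @param intercept Logit-scale intercept (default `qlogis(0.95)`).
#' @param slopes Length-4 logit-scale stress slopes.
#' @param phi Beta precision.
#' @param seed Seed.
#' @return Data frame `sample_id`, `prop_purifying`.
#' @export
simulate_population_selection <- function(stress,
                                          intercept = stats::qlogis(0.95),
                                          slopes = c(acidity = 0, aridity = 0,
                                                     heat = -0.4, salinity = -0.4),
                                          phi = 60, seed = 1L) {
  X <- stress_matrix(stress)
  if (length(slopes) != 4L) stopf("'slopes' must have length 4")
  if (is.null(names(slopes))) names(slopes) <- STRESS_NAMES
  mu <- stats::plogis(intercept + as.numeric(X %*% slopes[STRESS_NAMES]))
  with_seed(seed, {
    data.frame(sample_id = rownames(X),
               prop_purifying = stats::rbeta(nrow(X), mu * phi, (1 - mu) * phi),
               stringsAsFactors = FALSE)
  })
}

#' Simulate gene positions on a circular genome
#'
#' Accessory genes are placed uniformly on the circle, except that core
#' genes and stress-neutral accessory genes (max |z| below `neutral_band`)
#' are enriched inside the planted hotspot interval by the configured
#' density factor. Positions are 0-based, half-open, unique.
#'
#' @param gene_ids Gene identifiers to place.
#' @param labels Named `core` / `accessory` labels covering `gene_ids`.
#' @param z Optional named max-|z| summary per accessory gene used for the
#'   neutral-gene enrichment.
#' @param config A [simulation_config()].
#' @param neutral_band |z| below which an accessory gene counts as neutral.
#' @param seed Optional seed override.
#' @return A `genome_map` data frame (`gene_id`, `position`, `label`) with a
#'   `genome_length` attribute.
#' @export
simulate_genome_map <- function(gene_ids, labels, z = NULL, config,
                                neutral_band = 0.5, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  L <- config$genome_length
  n <- length(gene_ids)
  if (n > L) stopf("more genes (%d) than representable positions (%g)", n, L)
  lab <- labels[gene_ids]
  if (anyNA(lab)) stopf("labels missing for some gene_ids")
  hot <- config$hotspot_interval
  h <- hot[2] - hot[1]
  enr <- config$hotspot_enrichment
  w_enriched <- enr * h / (enr * h + (L - h))
  w_unif <- h / L
  neutral <- rep(FALSE, n)
  if (!is.null(z)) {
    zz <- z[gene_ids]
    neutral <- !is.na(zz) & abs(zz) < neutral_band
  }
  p_in <- ifelse(lab == "core" | neutral, w_enriched, w_unif)
  with_seed(seed %||% derive_seed(config$seed, 5L), {
    inside <- stats::runif(n) < p_in
    pos <- numeric(n)
    pos[inside] <- hot[1] + sample.int(h, sum(inside), replace = TRUE) - 1
    pos[!inside] <- (hot[2] + sample.int(L - h, sum(!inside), replace = TRUE) - 1) %% L
    # resolve collisions: redraw uniformly until unique
    while (anyDuplicated(pos)) {
      dupi <- which(duplicated(pos))
      pos[dupi] <- sample.int(L, length(dupi), replace = TRUE) - 1
    }
    genome_map(data.frame(gene_id = gene_ids, position = pos,
                          label = unname(lab), stringsAsFactors = FALSE),
               genome_length = L)
  })
}

#' Generate the complete set of synthetic pipeline inputs
#'
#' Orchestrates all generators under one configuration: design + raw
#' environment, stress profiles, interaction network, pangenome matrix, SNP
#' matrix, gene- and population-level selection summaries, and the genome
#' map, together with the planted ground truth.
#'
#' @param config A [simulation_config()].
#' @return List `design`, `environment`, `stress`, `network`, `pangenome`,
#'   `truth`, `snp`, `selection`, `population_selection`, `genome_map`,
#'   `config`.
#' @export
simulate_all <- function(config = simulation_config()) {
  des <- simulate_design(config)
  stress <- standardize_environment(des$environment)
  net <- simulate_network(config$n_genes, seed = derive_seed(config$seed, 6L))
  traits <- data.frame(gene_id = igraph::V(net)$name,
                       betweenness = unname(network_betweenness(net)),
                       mean_cosine = unname(mean_cosine(net)),
                       stringsAsFactors = FALSE)
  pg <- simulate_pangenome(des$design, stress, traits, config)
  snp <- simulate_snp_data(des$design, stress, config)
  sel <- simulate_selection_summaries(pg$truth$planted_category, config)
  pop_sel <- simulate_population_selection(stress,
                                           seed = derive_seed(config$seed, 7L))
  # plant the retention hotspot: neutral accessory genes and core genes
  # concentrate inside the hotspot interval
  zmax <- apply(pg$truth$true_beta, 1, function(b) b[which.max(abs(b))])
  lab <- ifelse(pg$matrix$labels == "core", "core", "accessory")
  names(lab) <- pg$matrix$genes
  gmap <- simulate_genome_map(pg$matrix$genes, lab, z = zmax, config = config)
  list(design = des$design, environment = des$environment, stress = stress,
       network = net, pangenome = pg$matrix, truth = pg$truth, snp = snp,
       selection = sel, population_selection = pop_sel, genome_map = gmap,
       config = config)
}

#' Write all synthetic inputs as plain tab-delimited files
#'
#' Writes the seven pipeline input tables plus a JSON ground-truth sidecar.
#'
#' @param sim Result of [simulate_all()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_simulation_inputs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(
    w(sim$design, "design.tsv"),
    w(sim$environment, "environment.tsv"),
    w(data.frame(strain_id = rownames(sim$pangenome$counts),
                 sim$pangenome$counts, check.names = FALSE),
      "gene_counts.tsv"),
    w(igraph::as_data_frame(sim$network, "edges")[, 1:2], "network_edges.tsv"),
    w(sim$selection, "selection_summaries.tsv"),
    w(sim$population_selection, "population_selection.tsv"),
    w(data.frame(strain_id = rownames(sim$snp$genotypes),
                 sample_id = unname(sim$snp$sample_of[rownames(sim$snp$genotypes)]),
                 sim$snp$genotypes, check.names = FALSE),
      "snp_matrix.tsv"),
    w(cbind(as.data.frame(sim$genome_map),
            genome_length = attr(sim$genome_map, "genome_length")),
      "genome_map.tsv"))
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(true_beta = as.data.frame(sim$truth$true_beta),
         planted_category = as.list(sim$truth$planted_category),
         true_richness_slopes = as.list(sim$truth$true_richness_slopes),
         hotspot_interval = sim$config$hotspot_interval,
         F_by_sample = as.list(sim$snp$truth$F_by_sample)),
    truth_path, digits = NA, auto_unbox = TRUE)
  invisible(c(paths, truth_path))
}
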