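# End-to-end orchestration: simulate (or load) inputs, run every analysis
# stage in dependency order, and assemble a four-column summary table of the
# key results per stress gradient.

#' Pipeline configuration
#'
#' @param simulate A [simulation_config()] describing synthetic inputs
#'   (the default), or `NULL` when `input_dir` points at pre-made tables
#'   written in the layout of [write_simulation_inputs()].
#' @param input_dir Directory of input tables when not simulating.
#' @param stages Character vector of stages to run; any of `"selection"`,
#'   `"fst"`, `"smoothing"` may be dropped (the core environment /
#'   pangenome / occurrence / trait stages always run).
#' @param core_threshold Core-gene label threshold.
#' @param z_threshold Loss-weight inclusion cutoff.
#' @param n_per_cat Target genes per stress-response category.
#' @param neutral_band |z| bound of the no-response stratification pool.
#' @param bins_k Number of environmental bins for Fst.
#' @param n_perm Permutations for the Fst test.
#' @param smoothing_max_points Genes per GP smoother fit.
#' @param seed Master seed (mandatory; drives every stochastic stage).
#' @param out_dir Optional directory for stage TSV outputs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = simulation_config(),
                            input_dir = NULL,
                            stages = c("selection", "fst", "smoothing"),
                            core_threshold = 0.99,
                            z_threshold = -2,
                            n_per_cat = 1000,
                            neutral_band = 0.5,
                            bins_k = 5L,
                            n_perm = 999L,
                            smoothing_max_points = 800L,
                            seed = 1L,
                            out_dir = NULL) {
  if (is.null(simulate) && is.null(input_dir)) {
    stopf("either a simulate block or an input_dir is required")
  }
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stopf("input_dir '%s' does not exist", input_dir)
  }
  assert_count(seed, "seed", min = 0L)
  structure(list(simulate = simulate, input_dir = input_dir, stages = stages,
                 core_threshold = core_threshold, z_threshold = z_threshold,
                 n_per_cat = n_per_cat, neutral_band = neutral_band,
                 bins_k = as.integer(bins_k),
                 n_perm = as.integer(n_perm),
                 smoothing_max_points = as.integer(smoothing_max_points),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

load_pipeline_inputs <- function(dir) {
  rd <- function(name, ...) utils::read.delim(file.path(dir, name),
                                              stringsAsFactors = FALSE, ...)
  cnt <- rd("gene_counts.tsv", check.names = FALSE)
  counts <- as.matrix(cnt[, -1, drop = FALSE])
  rownames(counts) <- cnt[[1]]
  snp_tab <- rd("snp_matrix.tsv", check.names = FALSE)
  G <- as.matrix(snp_tab[, -(1:2), drop = FALSE])
  rownames(G) <- snp_tab$strain_id
  gm <- rd("genome_map.tsv")
  list(design = rd("design.tsv"), environment = rd("environment.tsv"),
       pangenome = pangenome_matrix(counts),
       network = build_network(rd("network_edges.tsv"),
                               isolated_genes = colnames(counts)),
       selection = rd("selection_summaries.tsv"),
       population_selection = rd("population_selection.tsv"),
       snp = list(genotypes = G,
                  sample_of = stats::setNames(snp_tab$sample_id,
                                              snp_tab$strain_id)),
       genome_map = genome_map(gm[c("gene_id", "position", "label")],
                               genome_length = gm$genome_length[1]),
       truth = NULL)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order (environment -> pangenome ->
#' occurrence -> traits -> meta-regression / loss -> selection -> Fst ->
#' smoothing), collecting per-stage status and timing plus the fitted
#' objects, and assembles a per-stress summary of the key results: richness
#' slope, mean gene z-score, trait interaction signs, environment-exclusive
#' loss counts, the population selection-efficiency slope and the Fst trend.
#' Deterministic given the configuration (including its seed).
#'
#' @param config A [pipeline_config()].
#' @param progress Print stage progress?
#' @return A `run_report`: list with `stages`, `results`, `summary`,
#'   `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), progress = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- list()
  results <- list()
  t0 <- proc.time()[["elapsed"]]
  say <- function(...) if (progress) message(sprintf(...))
  run_stage <- function(name, expr) {
    ts <- proc.time()[["elapsed"]]
    say("stage %s ...", name)
    val <- tryCatch(expr, error = function(e) {
      stopf("stage '%s' failed: %s (check the corresponding inputs/config)",
            name, conditionMessage(e))
    })
    stages[[name]] <<- list(status = "ok",
                            seconds = round(proc.time()[["elapsed"]] - ts, 2))
    val
  }

  inputs <- run_stage("inputs", {
    if (!is.null(config$simulate)) simulate_all(config$simulate)
    else load_pipeline_inputs(config$input_dir)
  })
  results$truth <- inputs$truth
  results$genome_map <- inputs$genome_map

  stress <- run_stage("environment", standardize_environment(inputs$environment))
  results$stress <- stress

  pg <- run_stage("pangenome", {
    pm <- classify_genes(inputs$pangenome, config$core_threshold)
    fm <- filter_for_richness(pm)
    list(matrix = pm, filtered = fm, richness = gene_richness(fm),
         diversity = pangenome_diversity(fm, inputs$design))
  })
  results$pangenome <- pg

  occ <- run_stage("occurrence", {
    rich_fit <- fit_richness_model(pg$richness, stress, inputs$design)
    div_fit <- fit_diversity_model(pg$diversity, stress, inputs$design)
    resp <- fit_gene_occurrence_models(pg$filtered, stress, inputs$design,
                                       progress = progress)
    list(richness_fit = rich_fit, diversity_fit = div_fit, responses = resp,
         z_summary = summarize_z(resp))
  })
  results$occurrence <- occ

  traits <- run_stage("traits", {
    tr <- gene_traits(inputs$network, pg$filtered)
    tr[stats::complete.cases(tr), , drop = FALSE]
  })
  results$traits <- traits

  loss <- run_stage("trait_loss", {
    z <- z_matrix(occ$responses)
    zl <- data.frame(gene_id = rep(rownames(z), 4),
                     environment = rep(STRESS_NAMES, each = nrow(z)),
                     z = as.vector(z), stringsAsFactors = FALSE)
    zl <- zl[zl$gene_id %in% traits$gene_id, ]
    reg <- fit_trait_regression(zl, traits)
    lw <- loss_weights(occ$responses, z_threshold = config$z_threshold)
    spec <- specificity_summary(lw)
    cat_test <- if (!is.null(inputs$truth$functional_category)) {
      category_effect_test(occ$responses, inputs$truth$functional_category)
    }
    list(regression = reg, loss_weights = lw, specificity = spec,
         category_test = cat_test)
  })
  results$trait_loss <- loss

  if ("selection" %in% config$stages) {
    results$selection <- run_stage("selection", {
      strata <- stratify_genes_by_z(occ$responses, n_per_cat = config$n_per_cat,
                                    neutral_band = config$neutral_band,
                                    seed = derive_seed(config$seed, 11L))
      sel <- inputs$selection
      si <- match(strata$gene_id, sel$gene_id)
      ok <- !is.na(si)
      df <- data.frame(category = factor(strata$category[ok],
                                         levels = c("none", "decrease", "increase")),
                       prop = sel$prop_purifying[si[ok]],
                       pos = sel$any_positive[si[ok]])
      beta_fit <- fit_beta_regression(df$prop, df["category"])
      pos_fit <- fit_positive_selection_model(df$pos, df$category)
      pop_fit <- population_dnds_model(inputs$population_selection, stress)
      list(strata = strata, beta_fit = beta_fit, positive_fit = pos_fit,
           population_fit = pop_fit)
    })
  } else stages$selection <- list(status = "skipped", seconds = 0)

  if ("fst" %in% config$stages) {
    results$fst <- run_stage("fst", {
      bins <- bin_samples_by_stress(stress, k = config$bins_k)
      pairs <- within_bin_pairs(bins)
      fp <- pairwise_fst(inputs$snp$genotypes, inputs$snp$sample_of, pairs)
      reg <- fst_stress_regression(fp, stress, n_perm = config$n_perm,
                                   seed = derive_seed(config$seed, 12L))
      list(bins = bins, pairs = fp, regression = reg)
    })
  } else stages$fst <- list(status = "skipped", seconds = 0)

  if ("smoothing" %in% config$stages) {
    results$smoothing <- run_stage("smoothing", {
      z <- z_matrix(occ$responses)
      gm <- inputs$genome_map
      tracks <- lapply(stats::setNames(STRESS_NAMES, STRESS_NAMES), function(e) {
        fit_circular_smoother(gm, z[, e],
                              max_points = config$smoothing_max_points,
                              seed = derive_seed(config$seed, 13L))
      })
      hotspots <- lapply(tracks, detect_retention_hotspots)
      core_dens <- core_density_track(gm)
      coloc <- lapply(stats::setNames(STRESS_NAMES, STRESS_NAMES), function(e) {
        if (nrow(hotspots[[e]]) == 0) return(list(jaccard = 0, p = NA_real_))
        core_colocation_test(hotspots[[e]], gm,
                             seed = derive_seed(config$seed, 14L))
      })
      list(tracks = tracks, hotspots = hotspots, core_density = core_dens,
           colocation = coloc)
    })
  } else stages$smoothing <- list(status = "skipped", seconds = 0)

  summary_tab <- build_summary_table(results)
  if (!is.null(config$out_dir)) write_report_outputs(results, summary_tab,
                                                     config$out_dir)
  structure(list(stages = stages, results = results, summary = summary_tab,
                 config = config,
                 elapsed = round(proc.time()[["elapsed"]] - t0, 2)),
            class = "run_report")
}

# Per-stress summary in the shape of a key-results table.
build_summary_table <- function(results) {
  occ <- results$occurrence
  reg <- results$trait_loss$regression
  spec <- results$trait_loss$specificity
  rows <- lapply(STRESS_NAMES, function(e) {
    rich_b <- unname(occ$richness_fit$coefficients[e])
    rich_p <- unname(occ$richness_fit$p[e])
    mz <- occ$z_summary$table$mean_z[occ$z_summary$table$environment == e]
    ints <- reg$interactions[reg$interactions$environment == e, ]
    sig <- ints$trait[ints$p < 0.05]
    trait_txt <- if (length(sig)) {
      paste(sprintf("%s(%s)", sig,
                    ifelse(ints$estimate[match(sig, ints$trait)] < 0,
                           "loss", "retention")), collapse = ", ")
    } else "none"
    fst_b <- if (!is.null(results$fst)) results$fst$regression$slopes[e] else NA
    fst_p <- if (!is.null(results$fst)) results$fst$regression$p_perm[e] else NA
    pop_b <- if (!is.null(results$selection) &&
                 isTRUE(results$selection$population_fit$converged)) {
      unname(results$selection$population_fit$coefficients[e])
    } else NA
    data.frame(stress = e,
               richness_slope = rich_b, richness_p = rich_p,
               mean_z = mz,
               trait_predictors = trait_txt,
               exclusive_loss_n = unname(spec$counts[e]),
               selection_slope = pop_b,
               fst_slope = unname(fst_b), fst_p = unname(fst_p),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

write_report_outputs <- function(results, summary_tab, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) utils::write.table(df, file.path(out_dir, name),
                                             sep = "\t", quote = FALSE,
                                             row.names = FALSE)
  w(summary_tab, "summary.tsv")
  w(results$occurrence$responses, "gene_z_scores.tsv")
  w(results$traits, "gene_traits.tsv")
  if (!is.null(results$trait_loss$loss_weights)) {
    w(results$trait_loss$loss_weights, "loss_weights.tsv")
  }
  if (!is.null(results$fst)) w(results$fst$pairs, "fst_pairs.tsv")
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("stresspan run report\n")
  st <- vapply(x$stages, function(s) s$status, character(1))
  tm <- vapply(x$stages, function(s) s$seconds, numeric(1))
  cat(paste(sprintf("  %-12s %-8s %6.1fs", names(st), st, tm),
            collapse = "\n"), "\n")
  cat(sprintf("total elapsed: %.1fs\n\n", x$elapsed))
  cat("Key results by stress gradient:\n")
  tab <- x$summary
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) signif(v, 3))
  print(tab, row.names = FALSE)
  invisible(x)
}
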