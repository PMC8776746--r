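# Shared fixture builders: tiny designs, stress profiles and matrices built
# in code at test time.

make_design <- function(n_sites = 4, samples_per_site = 3, strains_per_sample = 5) {
  site <- sprintf("site%02d", seq_len(n_sites))
  samp <- as.vector(t(outer(site, seq_len(samples_per_site), paste, sep = "_s")))
  data.frame(
    strain_id = sprintf("%s_i%d", rep(samp, each = strains_per_sample),
                        rep(seq_len(strains_per_sample), length(samp))),
    sample_id = rep(samp, each = strains_per_sample),
    site_id = rep(rep(site, each = samples_per_site), each = strains_per_sample),
    stringsAsFactors = FALSE)
}

# Standardized stress profile drawn from independent normals.
make_stress <- function(design, seed = 1) {
  samples <- unique(design$sample_id)
  set.seed(seed)
  x <- matrix(rnorm(length(samples) * 4), ncol = 4)
  x <- scale(x)
  out <- data.frame(sample_id = samples, acidity = x[, 1], aridity = x[, 2],
                    heat = x[, 3], salinity = x[, 4], stringsAsFactors = FALSE)
  class(out) <- c("stress_profile", "data.frame")
  out
}

make_counts <- function(n_strains = 10, n_genes = 20, seed = 1, p = 0.5) {
  set.seed(seed)
  m <- matrix(rbinom(n_strains * n_genes, 2, p / 2), n_strains, n_genes,
              dimnames = list(sprintf("s%02d", seq_len(n_strains)),
                              sprintf("g%03d", seq_len(n_genes))))
  m
}

# z matrix with gene rownames and the four stress columns.
make_z <- function(z_rows) {
  m <- do.call(rbind, z_rows)
  colnames(m) <- c("acidity", "aridity", "heat", "salinity")
  rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  m
}

random_graph <- function(n, p, seed) {
  set.seed(seed)
  el <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  el <- el[runif(nrow(el)) < p, , drop = FALSE]
  ids <- sprintf("v%02d", seq_len(n))
  build_network(data.frame(a = ids[el[, 1]], b = ids[el[, 2]]),
                isolated_genes = ids)
}
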