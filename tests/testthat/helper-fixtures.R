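# Shared fixtures, built in code.

# 6 samples x 10 peaks: 2 single-event peaks, 3 detected in 2/6 samples,
# 5 detected in >= 3/6 samples -> exactly 5 survive the detection filter.
make_filter_fixture <- function() {
  x <- matrix(0, 6, 10, dimnames = list(paste0("s", 1:6), paste0("pk", 1:10)))
  x[1, 1] <- 5                      # single event
  x[4, 2] <- 3                      # single event
  x[1:2, 3] <- 1; x[3:4, 4] <- 1; x[5:6, 5] <- 1   # 2/6 detection
  x[1:3, 6] <- 1                    # 3/6 (boundary, retained)
  x[1:4, 7] <- 1
  x[1:5, 8] <- 1
  x[, 9] <- 1
  x[2:6, 10] <- 2
  peak_table(x, ppm = seq(1, 2.8, by = 0.2))
}

# Small null (no planted effects) configuration.
null_config <- function(seed, n_genes = 200, n_mirnas = 20) {
  synthetic_config(n_horses = 10, n_metabolites = 10, n_genes = n_genes,
                   n_mirnas = n_mirnas, n_pathways = 5, genes_per_pathway = 10,
                   n_active_metabolites = 0, n_active_regulators = 0,
                   frac_de_genes = 0, seed = seed)
}

# A centered vector orthogonalized against another, unit-norm.
orthogonalize <- function(v, against) {
  v <- v - mean(v)
  for (a in as.data.frame(against)) {
    a <- a - mean(a)
    v <- v - sum(v * a) / sum(a * a) * a
  }
  v / sqrt(sum(v^2))
}
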