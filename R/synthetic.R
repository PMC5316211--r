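# Synthetic paired two-timepoint multi-omic cohorts with planted,
# ground-truthed structure.
#
# Design notes (full rationale in the methods vignette):
# * Every feature's noise is a unit-variance mix of a per-horse intercept
#   (30% of variance, shared across the two timepoints) and per-sample
#   noise, so the paired design is present in every layer.
# * Planted metabolite-gene couplings share a standardized latent factor:
#   both sides load it with sqrt(latent_coupling), giving an expected
#   pairwise Pearson correlation equal to latent_coupling.
# * Metabolite peak intensities are log-normal (log-scale sd 0.4, ~40% CV,
#   typical of serum NMR areas) and total-area normalized per sample;
#   expression values are Gaussian on the log2 scale with sd `noise_sd`.
# * Active regulators are miRNAs whose (standardized) signal is mixed into
#   their target DE genes at T1 only, creating the condition-dependent
#   co-expression that RIF is built to detect.

.HORSE_SHARE <- 0.3    # fraction of residual variance shared within horse
.METAB_LOG_SD <- 0.4   # log-scale sd of peak intensities
.REG_MIX <- 1.0        # regulator signal weight mixed into targets at T1

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a paired endurance-ride style cohort: 20 horses
#' sampled at T0 and T1, 30 metabolite peaks of which 5 shift at T1 with a
#' standardized effect of 1.5, pathway blocks of 20 genes coupled to the
#' active metabolites at correlation 0.8, 10% differentially expressed
#' genes, and 3 active miRNA regulators.
#'
#' @param n_horses,n_metabolites,n_genes,n_mirnas,n_pathways counts.
#' @param genes_per_pathway genes per pathway block; `n_pathways *
#'   genes_per_pathway` must not exceed `n_genes`.
#' @param n_active_metabolites number of planted differential metabolites
#'   (0 allowed: pure-null generator).
#' @param effect_size_metab standardized T1 - T0 mean shift of active
#'   metabolites (log scale).
#' @param latent_coupling target within-block metabolite-gene correlation,
#'   in `[0, 1]`.
#' @param n_active_regulators number of planted differentially
#'   co-expressed miRNA regulators (0 allowed).
#' @param frac_de_genes fraction of genes (and miRNAs) differentially
#'   expressed, in `[0, 1)`.
#' @param noise_sd residual sd of expression values (log2 units), > 0.
#' @param seed integer seed; all generator draws derive from it.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_horses = 20, n_metabolites = 30,
                             n_genes = 1000, n_mirnas = 100,
                             n_pathways = 10, genes_per_pathway = 20,
                             n_active_metabolites = 5,
                             effect_size_metab = 1.5,
                             latent_coupling = 0.8,
                             n_active_regulators = 3,
                             frac_de_genes = 0.1,
                             noise_sd = 1, seed = 1) {
  cfg <- list(n_horses = n_horses, n_metabolites = n_metabolites,
              n_genes = n_genes, n_mirnas = n_mirnas,
              n_pathways = n_pathways, genes_per_pathway = genes_per_pathway,
              n_active_metabolites = n_active_metabolites,
              effect_size_metab = effect_size_metab,
              latent_coupling = latent_coupling,
              n_active_regulators = n_active_regulators,
              frac_de_genes = frac_de_genes,
              noise_sd = noise_sd, seed = as.integer(seed))
  counts <- c("n_horses", "n_metabolites", "n_genes", "n_mirnas",
              "n_pathways", "genes_per_pathway")
  for (f in counts)
    if (cfg[[f]] < 1) stop(f, " must be at least 1")
  if (n_active_metabolites < 0 || n_active_metabolites > n_metabolites)
    stop("n_active_metabolites must lie in [0, n_metabolites]")
  if (n_active_regulators < 0 || n_active_regulators > n_mirnas)
    stop("n_active_regulators must lie in [0, n_mirnas]")
  if (latent_coupling < 0 || latent_coupling > 1)
    stop("latent_coupling must lie in [0, 1]")
  if (frac_de_genes < 0 || frac_de_genes >= 1)
    stop("frac_de_genes must lie in [0, 1)")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (n_pathways * genes_per_pathway > n_genes)
    stop("n_pathways * genes_per_pathway must not exceed n_genes")
  if (n_active_metabolites > n_pathways)
    stop("need at least one pathway per active metabolite")
  structure(cfg, class = "synthetic_config")
}

# Unit-variance residual matrix for `p` features over the paired samples:
# per-horse intercept worth .HORSE_SHARE of the variance plus iid noise.
.paired_resid <- function(n_horses, p) {
  a <- sqrt(.HORSE_SHARE)
  b <- matrix(stats::rnorm(n_horses * p), n_horses, p)
  e <- matrix(stats::rnorm(2 * n_horses * p), 2 * n_horses, p)
  a * rbind(b, b) + sqrt(1 - .HORSE_SHARE) * e
}

#' Generate the pathway database for a configuration
#'
#' Pathway gene sets partition the first `n_pathways * genes_per_pathway`
#' genes; a positive `overlap_jaccard` replaces part of every pathway's
#' genes with a common shared core sized so the mean pairwise Jaccard
#' index of the gene sets equals the target. Each active metabolite gets a
#' dedicated pathway (its planted gene block); inactive metabolites are
#' spread round-robin over the remaining pathways. Every pathway carries a
#' directed chain graph over its metabolites.
#'
#' @param config a [synthetic_config()].
#' @param overlap_jaccard target mean pairwise Jaccard of pathway gene
#'   sets, in `[0, 1)` (default 0: disjoint).
#' @return a [pathway_db()].
#' @export
generate_pathway_db <- function(config, overlap_jaccard = 0) {
  stopifnot(inherits(config, "synthetic_config"),
            overlap_jaccard >= 0, overlap_jaccard < 1)
  set.seed(.derive_seed(config$seed, 11L))
  g <- config$genes_per_pathway
  np <- config$n_pathways
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  mets <- sprintf("met%02d", seq_len(config$n_metabolites))
  blocks <- split(genes[seq_len(np * g)], rep(seq_len(np), each = g))
  if (overlap_jaccard > 0 && np > 1L) {
    s <- 2 * overlap_jaccard / (1 + overlap_jaccard)  # shared-core fraction
    n_core <- round(s * g)
    core <- blocks[[1L]][seq_len(n_core)]
    blocks <- lapply(blocks, function(b) c(core, setdiff(b, core)[seq_len(g - n_core)]))
  }
  n_act <- config$n_active_metabolites
  assign <- integer(config$n_metabolites)
  assign[seq_len(n_act)] <- seq_len(n_act)
  rest <- setdiff(seq_len(config$n_metabolites), seq_len(n_act))
  free <- setdiff(seq_len(np), seq_len(n_act))
  if (length(free) == 0L) free <- seq_len(np)
  assign[rest] <- rep_len(free, length(rest))
  pw <- list()
  for (k in seq_len(np)) {
    mk <- mets[assign == k]
    edges <- if (length(mk) >= 2L)
      cbind(mk[-length(mk)], mk[-1L]) else matrix(character(0), 0, 2)
    pw[[sprintf("P%02d", k)]] <- list(name = sprintf("pathway %d", k),
                                      genes = blocks[[k]],
                                      metabolites = mk,
                                      edges = edges)
  }
  pathway_db(pw)
}

#' Generate a synthetic paired cohort
#'
#' Produces the peak table, gene and miRNA expression matrices, sample
#' metadata, reference chemical-shift table, pathway database and exact
#' ground truth for one simulated cohort. Active metabolites are the first
#' `n_active_metabolites` metabolite ids, each coupled to its dedicated
#' pathway's gene block (all of which are differentially expressed);
#' active regulators are the first `n_active_regulators` miRNA ids, mixed
#' into their (non-coupled) target DE genes at T1 only.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_cohort`: `peaks` ([peak_table()]),
#'   `genes`, `mirnas` (samples x features log2 matrices), `metadata`
#'   (`sample_id`, `horse`, `timepoint`, `status`), `ref_shifts`
#'   (reference chemical-shift table), `pathways` ([pathway_db()]),
#'   `truth` (`active_metabolites`, `de_genes`, `de_mirnas`,
#'   `active_regulators`, `metabolite_gene_pairs`, `regulator_targets`,
#'   `metabolite_direction`), `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  db <- generate_pathway_db(config)
  set.seed(.derive_seed(config$seed, 29L))
  H <- config$n_horses
  n <- 2L * H
  horses <- sprintf("H%02d", seq_len(H))
  sample_ids <- c(paste0(horses, "_T0"), paste0(horses, "_T1"))
  tp <- rep(c("T0", "T1"), each = H)
  z1 <- as.numeric(tp == "T1")
  metadata <- data.frame(
    sample_id = sample_ids, horse = rep(horses, 2), timepoint = tp,
    status = rep(ifelse(stats::runif(H) < 0.7, "finish", "eliminated"), 2),
    row.names = NULL)

  mets <- sprintf("met%02d", seq_len(config$n_metabolites))
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  mirs <- sprintf("mir%03d", seq_len(config$n_mirnas))
  n_act <- config$n_active_metabolites
  active_mets <- mets[seq_len(n_act)]
  rho <- config$latent_coupling

  # one standardized latent per active metabolite (horse share built in)
  latents <- if (n_act > 0) .paired_resid(H, n_act) else NULL

  # ---- metabolite peak table -------------------------------------------
  met_shift_sign <- ifelse(stats::runif(config$n_metabolites) < 0.5, 1, -1)
  mu_met <- stats::rnorm(config$n_metabolites, mean = 2.5, sd = 0.8)
  resid_m <- .paired_resid(H, config$n_metabolites)
  logI <- matrix(0, n, config$n_metabolites)
  for (j in seq_len(config$n_metabolites)) {
    r <- resid_m[, j]
    delta <- 0
    if (j <= n_act) {
      r <- sqrt(rho) * latents[, j] + sqrt(1 - rho) * r
      delta <- met_shift_sign[j] * config$effect_size_metab
    }
    logI[, j] <- mu_met[j] + .METAB_LOG_SD * (delta * z1 + r)
  }
  intens <- exp(logI)
  intens <- intens / rowSums(intens) * 100
  ref_ppm <- sort(stats::runif(config$n_metabolites, 0.8, 9.5))
  ppm <- ref_ppm + stats::runif(config$n_metabolites, -0.003, 0.003)
  dimnames(intens) <- list(sample_ids, mets)
  peaks <- peak_table(intens, ppm)
  ref_shifts <- data.frame(metabolite = mets, reference_ppm = ref_ppm,
                           multiplicity = "s", row.names = NULL)

  # ---- gene expression -------------------------------------------------
  coupled <- do.call(rbind, lapply(seq_len(n_act), function(j) {
    data.frame(metabolite = active_mets[j],
               gene = db$pathways[[sprintf("P%02d", j)]]$genes)
  }))
  if (is.null(coupled))
    coupled <- data.frame(metabolite = character(0), gene = character(0))
  coupled_genes <- unique(coupled$gene)
  n_extra_min <- 10L * config$n_active_regulators
  n_de_target <- max(round(config$frac_de_genes * config$n_genes),
                     length(coupled_genes) + n_extra_min)
  n_de_target <- min(n_de_target, config$n_genes)
  pool <- setdiff(genes, coupled_genes)
  extra <- if (n_de_target > length(coupled_genes))
    sample(pool, n_de_target - length(coupled_genes)) else character(0)
  de_genes <- c(coupled_genes, extra)

  base_g <- stats::rnorm(config$n_genes, 8, 2)
  lfc <- stats::setNames(numeric(config$n_genes), genes)
  lfc[extra] <- config$noise_sd *
    sample(c(-1, 1), length(extra), TRUE) * stats::runif(length(extra), 0.75, 1.5)
  if (nrow(coupled)) {
    sgn <- met_shift_sign[match(coupled$metabolite, mets)]
    mag <- config$noise_sd * stats::runif(nrow(coupled), 0.75, 1.5)
    lfc[coupled$gene] <- sgn * mag      # co-regulated with their metabolite
  }
  resid_g <- .paired_resid(H, config$n_genes)
  if (n_act > 0) {
    for (j in seq_len(n_act)) {
      cols <- match(db$pathways[[sprintf("P%02d", j)]]$genes, genes)
      resid_g[, cols] <- sqrt(rho) * latents[, j] +
        sqrt(1 - rho) * resid_g[, cols]
    }
  }
  gexpr <- matrix(rep(base_g, each = n), n, config$n_genes) +
    outer(z1, lfc[genes]) + config$noise_sd * resid_g
  dimnames(gexpr) <- list(sample_ids, genes)

  # ---- miRNA expression and regulator mixing ---------------------------
  n_reg <- config$n_active_regulators
  regulators <- mirs[seq_len(n_reg)]
  n_de_mir <- max(round(config$frac_de_genes * config$n_mirnas), n_reg)
  de_mirnas <- unique(c(regulators,
                        if (n_de_mir > n_reg)
                          sample(setdiff(mirs, regulators), n_de_mir - n_reg)))
  base_mir <- stats::rnorm(config$n_mirnas, 6, 1.5)
  lfc_mir <- stats::setNames(numeric(config$n_mirnas), mirs)
  lfc_mir[de_mirnas] <- config$noise_sd *
    sample(c(-1, 1), length(de_mirnas), TRUE) *
    stats::runif(length(de_mirnas), 0.75, 1.5)
  resid_mir <- .paired_resid(H, config$n_mirnas)
  mexpr <- matrix(rep(base_mir, each = n), n, config$n_mirnas) +
    outer(z1, lfc_mir[mirs]) + config$noise_sd * resid_mir
  dimnames(mexpr) <- list(sample_ids, mirs)

  reg_targets <- data.frame(regulator = character(0), gene = character(0))
  if (n_reg > 0 && length(extra) > 0) {
    split_idx <- rep_len(seq_len(n_reg), length(extra))
    reg_targets <- data.frame(regulator = regulators[split_idx], gene = extra)
    at_t1 <- which(z1 == 1)
    for (r in seq_len(n_reg)) {
      tg <- reg_targets$gene[reg_targets$regulator == regulators[r]]
      zreg <- resid_mir[at_t1, r]          # standardized regulator signal
      gexpr[at_t1, tg] <- gexpr[at_t1, tg] +
        config$noise_sd * .REG_MIX * zreg
    }
  }

  truth <- list(active_metabolites = active_mets,
                de_genes = sort(de_genes),
                de_mirnas = sort(de_mirnas),
                active_regulators = regulators,
                metabolite_gene_pairs = coupled,
                regulator_targets = reg_targets,
                metabolite_direction = stats::setNames(
                  ifelse(met_shift_sign > 0, "up", "down"), mets)[active_mets])
  structure(list(peaks = peaks, genes = gexpr, mirnas = mexpr,
                 metadata = metadata, ref_shifts = ref_shifts,
                 pathways = db, truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic cohort:", x$config$n_horses, "horses x 2 timepoints;",
      x$config$n_metabolites, "metabolites,",
      x$config$n_genes, "genes,", x$config$n_mirnas, "miRNAs\n")
  cat("planted:", length(x$truth$active_metabolites), "active metabolites,",
      length(x$truth$de_genes), "DE genes,",
      length(x$truth$active_regulators), "active regulators\n")
  invisible(x)
}

#' Generate a miRNA-target table for a cohort
#'
#' Each planted miRNA regulator receives validated target edges to at
#' least `min_planted_targets` metabolic genes (the planted
#' metabolite-coupled genes, falling back to DE genes when no metabolites
#' were planted). Decoy miRNA-gene pairs are then added independently at
#' rate `decoy_rate` over all remaining possible pairs.
#'
#' @param config a [synthetic_config()].
#' @param truth the `truth` element of [generate_cohort()].
#' @param decoy_rate inclusion probability of each non-planted pair
#'   (default 0.05).
#' @param min_planted_targets minimum validated targets per planted
#'   regulator (default 12; at least 10 whenever the gene pool allows).
#' @return data frame `mirna_id`, `gene_id`, `support`.
#' @export
generate_target_db <- function(config, truth, decoy_rate = 0.05,
                               min_planted_targets = 12) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(.derive_seed(config$seed, 47L))
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  mirs <- sprintf("mir%03d", seq_len(config$n_mirnas))
  pool <- unique(truth$metabolite_gene_pairs$gene)
  if (length(pool) == 0L) pool <- truth$de_genes
  planted <- data.frame(mirna_id = character(0), gene_id = character(0))
  for (r in truth$active_regulators) {
    if (length(pool) == 0L) break
    tg <- sample(pool, min(min_planted_targets, length(pool)))
    planted <- rbind(planted, data.frame(mirna_id = r, gene_id = tg))
  }
  out <- if (nrow(planted))
    data.frame(planted, support = "validated") else
    data.frame(mirna_id = character(0), gene_id = character(0),
               support = character(0))
  if (decoy_rate > 0) {
    all_pairs <- expand.grid(mirna_id = mirs, gene_id = genes,
                             KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    key <- paste(all_pairs$mirna_id, all_pairs$gene_id)
    pk <- paste(out$mirna_id, out$gene_id)
    cand <- all_pairs[!(key %in% pk), ]
    keep <- stats::runif(nrow(cand)) < decoy_rate
    if (any(keep))
      out <- rbind(out, data.frame(cand[keep, ], support = "validated"))
  }
  rownames(out) <- NULL
  out
}
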