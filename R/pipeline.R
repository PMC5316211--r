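# End-to-end orchestration: simulate/load -> peak prep -> chemometrics ->
# differential expression -> enrichment & network -> RIF -> MFA.

#' Pipeline configuration
#'
#' Collects the thresholds used across the stages (defaults are the
#' workflow's standard settings: correlation filter |r| > 0.5 at p < 0.05,
#' DE at BH q < 0.05, enrichment at FDR < 0.1, MFA high-weight threshold
#' 0.80, miRNA network-reduction rule of at least 10 metabolic targets,
#' assignment tolerance 0.005 ppm, 999 interclass and 1000 OPLS
#' permutations) together with either a [synthetic_config()] to simulate
#' inputs or a named list of input file paths.
#'
#' @param simulate a [synthetic_config()], or `NULL` to read `inputs`.
#' @param inputs named list of paths: `peaks`, `genes`, `mirnas`,
#'   `metadata`, `pathways`, `targets`, `ref_shifts`, `tf_list`.
#' @param r_thresh,p_thresh metabolite-DEG correlation filter.
#' @param de_q DE significance threshold (BH).
#' @param enrich_fdr metabolite enrichment FDR.
#' @param mfa_threshold high-weight correlation threshold.
#' @param min_targets miRNA network-reduction rule.
#' @param tol_ppm peak assignment tolerance.
#' @param min_detect_frac peak detection filter.
#' @param n_ortho orthogonal OPLS components.
#' @param n_perm_interclass,n_perm_opls permutation counts.
#' @param cv_folds OPLS cross-validation folds.
#' @param seed top-level seed; per-stage seeds are derived from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, inputs = NULL,
                            r_thresh = 0.5, p_thresh = 0.05,
                            de_q = 0.05, enrich_fdr = 0.1,
                            mfa_threshold = 0.80, min_targets = 10,
                            tol_ppm = 0.005, min_detect_frac = 0.5,
                            n_ortho = 1, n_perm_interclass = 999,
                            n_perm_opls = 1000, cv_folds = 10, seed = 1) {
  if (is.null(simulate) && is.null(inputs))
    stop("provide either a synthetic_config or input paths")
  stopifnot(r_thresh >= 0, r_thresh <= 1, p_thresh > 0, p_thresh <= 1,
            de_q > 0, de_q <= 1, enrich_fdr > 0, enrich_fdr <= 1,
            mfa_threshold >= 0, mfa_threshold <= 1,
            min_targets >= 1, tol_ppm > 0)
  structure(list(simulate = simulate, inputs = inputs,
                 r_thresh = r_thresh, p_thresh = p_thresh, de_q = de_q,
                 enrich_fdr = enrich_fdr, mfa_threshold = mfa_threshold,
                 min_targets = min_targets, tol_ppm = tol_ppm,
                 min_detect_frac = min_detect_frac, n_ortho = n_ortho,
                 n_perm_interclass = n_perm_interclass,
                 n_perm_opls = n_perm_opls, cv_folds = cv_folds,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Run the full integration pipeline
#'
#' Executes every stage on one cohort and serializes all intermediate and
#' final artifacts as plain TSV/JSON/GraphML under `out_dir`, together
#' with a provenance manifest (`manifest.json`: parameters, per-stage
#' output files and their md5 checksums). Reruns with the same
#' configuration and seed are bit-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return object of class `pipeline_run` with elements `cohort`, `prep`,
#'   `chemometrics`, `de`, `enrichment`, `network`, `pathway_impact`,
#'   `rif`, `mfa`, `notes`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("omicsweave_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  notes <- character(0)
  manifest <- list(parameters = unclass(config)[setdiff(names(config),
                                                        c("simulate", "inputs"))],
                   seed = config$seed, stages = list())
  record <- function(stage, files) {
    files <- files[file.exists(files)]
    manifest$stages[[stage]] <<- list(
      files = basename(files),
      md5 = unname(tools::md5sum(files)))
  }

  # -- stage 1: inputs ----------------------------------------------------
  if (!is.null(config$simulate)) {
    cohort <- generate_cohort(config$simulate)
    targets <- generate_target_db(config$simulate, cohort$truth)
    tf_list <- character(0)
    idir <- file.path(out_dir, "inputs")
    dir.create(idir, showWarnings = FALSE)
    write_peaks(cohort$peaks, file.path(idir, "peaks.csv"))
    write_expression(cohort$genes, file.path(idir, "genes.tsv"))
    write_expression(cohort$mirnas, file.path(idir, "mirnas.tsv"))
    .write_tsv(cohort$metadata, file.path(idir, "metadata.tsv"))
    utils::write.csv(cohort$ref_shifts, file.path(idir, "ref_shifts.csv"),
                     row.names = FALSE)
    write_pathway_db(cohort$pathways, file.path(idir, "pathways.json"))
    .write_tsv(targets, file.path(idir, "targets.tsv"))
    write_truth(cohort$truth, file.path(idir, "truth.json"))
    record("inputs", list.files(idir, full.names = TRUE))
  } else {
    inp <- config$inputs
    cohort <- list(
      peaks = read_peaks(inp$peaks),
      genes = read_expression(inp$genes),
      mirnas = read_expression(inp$mirnas),
      metadata = utils::read.delim(inp$metadata),
      ref_shifts = if (!is.null(inp$ref_shifts))
        utils::read.csv(inp$ref_shifts) else NULL,
      pathways = read_pathway_db(inp$pathways),
      truth = NULL)
    targets <- utils::read.delim(inp$targets)
    tf_list <- if (!is.null(inp$tf_list)) readLines(inp$tf_list) else character(0)
  }
  md <- cohort$metadata

  # -- stage 2: peak prep -------------------------------------------------
  pk <- filter_peaks(cohort$peaks, min_detect_frac = config$min_detect_frac)
  pk <- assign_peaks(pk, cohort$ref_shifts, tol_ppm = config$tol_ppm)
  ab <- pk$relative_abundance
  colnames(ab) <- make.unique(ifelse(pk$assignment != "unassigned",
                                     pk$assignment, pk$peak_ids))
  prep <- list(peaks = pk, abundance = ab)
  f <- file.path(out_dir, "abundance.tsv")
  write_expression(ab, f); record("prep", f)

  # -- stage 3: chemometrics ---------------------------------------------
  mrows <- match(rownames(ab), md$sample_id)
  labels <- factor(md$timepoint[mrows])
  horse <- factor(md$horse[mrows])
  pca <- fit_pca(ab)
  ict <- interclass_pca_test(ab, labels, n_perm = config$n_perm_interclass,
                             seed = .derive_seed(config$seed, 3L),
                             pair = horse)
  opls <- fit_opls(ab, labels, n_ortho = config$n_ortho,
                   k = min(config$cv_folds, nrow(ab)),
                   seed = .derive_seed(config$seed, 5L))
  perm <- permutation_validate(ab, labels, n = config$n_perm_opls,
                               seed = .derive_seed(config$seed, 7L),
                               n_ortho = config$n_ortho,
                               k = min(config$cv_folds, nrow(ab)),
                               pair = horse)
  selvars <- select_discriminant_variables(opls)
  selected <- selvars$variable[selvars$selected]
  anova <- anova_bonferroni(ab, labels)
  chem <- list(pca = pca, interclass = ict, opls = opls,
               permutation = perm, selection = selvars,
               selected = selected, anova = anova)
  files <- c(
    .write_tsv(data.frame(sample_id = rownames(pca$scores),
                          pca$scores[, seq_len(min(5, ncol(pca$scores)))]),
               file.path(out_dir, "pca_scores.tsv")),
    .write_tsv(selvars, file.path(out_dir, "loadings.tsv")),
    .write_tsv(selvars[selvars$selected, ],
               file.path(out_dir, "selected_metabolites.tsv")),
    .write_tsv(anova, file.path(out_dir, "anova.tsv")))
  jsonlite::write_json(
    list(observed = as.list(perm$observed),
         permuted_mean = as.list(perm$summary["mean", ]),
         permuted_sd = as.list(perm$summary["sd", ]),
         p_value = perm$p_value,
         interclass = list(statistic = ict$statistic, p_value = ict$p_value)),
    file.path(out_dir, "validation.json"), auto_unbox = TRUE, digits = NA)
  files <- c(files, file.path(out_dir, "validation.json"))
  record("chemometrics", files)

  # -- stage 4: differential expression ----------------------------------
  de_g <- paired_de_test(cohort$genes, md, q_thresh = config$de_q)
  de_m <- paired_de_test(cohort$mirnas, md, q_thresh = config$de_q)
  files <- c(.write_tsv(de_g, file.path(out_dir, "de_genes.tsv")),
             .write_tsv(de_m, file.path(out_dir, "de_mirnas.tsv")))
  record("de", files)

  # -- stage 5: enrichment and network -----------------------------------
  candidates <- intersect(selected, names(cohort$pathways$metabolite_index))
  enr <- enrich_metabolites(ab, cohort$genes, de_g, cohort$pathways,
                            candidates = candidates,
                            fdr = config$enrich_fdr,
                            r_thresh = config$r_thresh,
                            p_thresh = config$p_thresh)
  if (!any(enr$enriched)) notes <- c(notes, "no enriched metabolites")
  met_dir <- stats::setNames(ifelse(
    selvars$loading > 0, "up", "down"), selvars$variable)
  metabolic_union <- sort(unique(unlist(lapply(
    enr$metabolite[enr$enriched],
    function(m) intersect(
      suppressWarnings(metabolic_genes_for(m, cohort$pathways)),
      de_g$feature_id[de_g$significant])))))
  mo <- mirna_overlay(metabolic_union, targets, de_m,
                      min_targets = config$min_targets)
  net <- assemble_network(enr, cohort$pathways, de_g, de_m,
                          mirna_edges = mo, tf_list = tf_list,
                          metabolite_direction = met_dir)
  impact <- data.frame(
    pathway = names(cohort$pathways$pathways),
    impact = vapply(names(cohort$pathways$pathways), function(p)
      as.numeric(pathway_impact(cohort$pathways, p,
                                enr$metabolite[enr$enriched])),
      numeric(1)),
    row.names = NULL)
  files <- c(.write_tsv(as.data.frame(enr), file.path(out_dir, "enrichment.tsv")),
             .write_tsv(impact, file.path(out_dir, "pathway_impact.tsv")))
  if (nrow(net$edges)) {
    files <- c(files,
               write_network(net, file.path(out_dir, "network.graphml")),
               write_network(net, file.path(out_dir, "network.sif"),
                             format = "sif"))
  }
  record("enrichment", files)

  # -- stage 6: RIF -------------------------------------------------------
  i0 <- md$sample_id[md$timepoint == "T0"]
  i1 <- md$sample_id[md$timepoint == "T1"]
  degs <- de_g$feature_id[de_g$significant]
  rif <- NULL
  if (length(degs) == 0L) {
    notes <- c(notes, "no DE genes: RIF stage skipped")
  } else {
    regulators <- c(intersect(tf_list, colnames(cohort$genes)),
                    colnames(cohort$mirnas))
    kind <- stats::setNames(
      rep(c("tf", "mirna"),
          c(length(intersect(tf_list, colnames(cohort$genes))),
            ncol(cohort$mirnas))), regulators)
    rif <- compute_rif(cohort$genes[i0, , drop = FALSE],
                       cohort$genes[i1, , drop = FALSE],
                       de_genes = degs, regulators = regulators,
                       extra_c1 = cohort$mirnas[i0, , drop = FALSE],
                       extra_c2 = cohort$mirnas[i1, , drop = FALSE],
                       kind = kind)
    record("rif", .write_tsv(as.data.frame(rif),
                             file.path(out_dir, "rif.tsv")))
  }

  # -- stage 7: MFA per timepoint ----------------------------------------
  mfa <- list()
  for (tpt in c("T0", "T1")) {
    ids <- md$sample_id[md$timepoint == tpt]
    tabs <- list(metabolome = ab[ids, , drop = FALSE],
                 transcriptome = cohort$genes[ids, , drop = FALSE],
                 mirnome = cohort$mirnas[ids, , drop = FALSE])
    m <- fit_mfa(tabs)
    mfa[[tpt]] <- list(
      model = m,
      high_weights = high_weight_variables(m, 1, config$mfa_threshold),
      rv = m$rv)
    files <- c(
      .write_tsv(data.frame(sample_id = rownames(m$global_scores),
                            m$global_scores[, seq_len(min(5, ncol(m$global_scores)))]),
                 file.path(out_dir, paste0("mfa_scores_", tpt, ".tsv"))),
      .write_tsv(data.frame(table = rownames(m$rv), m$rv),
                 file.path(out_dir, paste0("mfa_rv_", tpt, ".tsv"))),
      .write_tsv(mfa[[tpt]]$high_weights,
                 file.path(out_dir, paste0("mfa_high_weights_", tpt, ".tsv"))))
    record(paste0("mfa_", tpt), files)
  }

  manifest$notes <- notes
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  structure(list(cohort = cohort, targets = targets, prep = prep,
                 chemometrics = chem, de = list(genes = de_g, mirnas = de_m),
                 enrichment = enr, network = net, pathway_impact = impact,
                 rif = rif, mfa = mfa, notes = notes,
                 out_dir = out_dir, manifest = manifest),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline run ->", x$out_dir, "\n")
  cat(sprintf("OPLS: R2 = %.2f, Q2 = %.2f (perm p = %.3g)\n",
              x$chemometrics$opls$R2, x$chemometrics$opls$cv$Q2,
              x$chemometrics$permutation$p_value))
  cat(length(x$chemometrics$selected), "discriminant metabolites;",
      sum(x$de$genes$significant), "DE genes;",
      sum(x$de$mirnas$significant), "DE miRNAs;",
      sum(x$enrichment$enriched), "enriched metabolites\n")
  print(x$network)
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
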