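# Metabolite -> metabolic-gene enrichment, miRNA overlay, pathway impact.

#' Construct a pathway database
#'
#' Maps metabolites to pathways, pathways to metabolic gene sets, and
#' carries a directed metabolite graph per pathway (metabolic networks are
#' directed). A metabolite or gene may belong to several pathways.
#'
#' @param pathways named list; each element a list with `name` (character),
#'   `genes` (character vector), `metabolites` (character vector) and
#'   `edges` (2-column matrix/list of directed metabolite edges, possibly
#'   empty).
#' @return object of class `pathway_db` with elements `pathways` and
#'   `metabolite_index` (metabolite -> pathway ids).
#' @export
pathway_db <- function(pathways) {
  stopifnot(is.list(pathways), length(names(pathways)) == length(pathways))
  for (id in names(pathways)) {
    p <- pathways[[id]]
    if (is.null(p$name)) pathways[[id]]$name <- id
    e <- p$edges
    if (is.null(e) || length(e) == 0L) {
      e <- matrix(character(0), 0, 2)
    } else if (is.matrix(e) || is.data.frame(e)) {
      e <- matrix(as.character(as.matrix(e)), ncol = 2)
    } else {
      e <- do.call(rbind, lapply(e, function(pr) as.character(pr[1:2])))
    }
    if (nrow(e) && !all(e %in% p$metabolites))
      stop("pathway ", id, ": edge endpoints must be pathway metabolites")
    pathways[[id]]$edges <- e
  }
  idx <- list()
  for (id in names(pathways))
    for (m in pathways[[id]]$metabolites)
      idx[[m]] <- c(idx[[m]], id)
  structure(list(pathways = pathways, metabolite_index = idx),
            class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  cat("pathway_db:", length(x$pathways), "pathways,",
      length(x$metabolite_index), "indexed metabolites\n")
  invisible(x)
}

#' Metabolic genes of a metabolite
#'
#' Union of the gene sets of every pathway the metabolite participates in;
#' these genes are the metabolite's "targets" in the regulatory network.
#' Unknown metabolites yield an empty set with a warning.
#'
#' @param metabolite metabolite id.
#' @param db a [pathway_db()].
#' @return character vector of gene ids (possibly empty).
#' @export
metabolic_genes_for <- function(metabolite, db) {
  stopifnot(inherits(db, "pathway_db"))
  pids <- db$metabolite_index[[metabolite]]
  if (is.null(pids)) {
    warning("metabolite not indexed in pathway database: ", metabolite)
    return(character(0))
  }
  sort(unique(unlist(lapply(db$pathways[pids], `[[`, "genes"))))
}

#' Correlate a metabolite with differentially expressed genes
#'
#' Pearson correlation of the metabolite's per-sample abundance with each
#' DEG across the pooled paired samples; a DEG is retained when `|r| >
#' r_thresh` (strict) and the unadjusted correlation p-value is below
#' `p_thresh`.
#'
#' @param metab_abund named numeric vector of metabolite abundance per
#'   sample.
#' @param expr samples x DEGs expression matrix with matching row names.
#' @param r_thresh correlation magnitude threshold (default 0.5, strict).
#' @param p_thresh unadjusted p-value threshold (default 0.05).
#' @return data frame `gene`, `r`, `p` for the retained DEGs.
#' @export
correlate_metabolite_degs <- function(metab_abund, expr,
                                      r_thresh = 0.5, p_thresh = 0.05) {
  expr <- as.matrix(expr)
  if (ncol(expr) == 0L)
    return(data.frame(gene = character(0), r = numeric(0), p = numeric(0)))
  common <- intersect(names(metab_abund), rownames(expr))
  if (length(common) < 3L) stop("fewer than 3 aligned samples")
  v <- metab_abund[common]
  e <- expr[common, , drop = FALSE]
  if (stats::sd(v) < .Machine$double.eps) {
    warning("zero-variance metabolite vector: no correlations computed")
    return(data.frame(gene = character(0), r = numeric(0), p = numeric(0)))
  }
  sds <- sqrt(colSums(sweep(e, 2L, colMeans(e), "-")^2))
  flat <- sds < .Machine$double.eps
  if (any(flat)) {
    warning(sum(flat), " zero-variance gene(s) skipped")
    e <- e[, !flat, drop = FALSE]
  }
  if (ncol(e) == 0L)
    return(data.frame(gene = character(0), r = numeric(0), p = numeric(0)))
  r <- c(stats::cor(v, e))
  n <- length(v)
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  keep <- abs(r) > r_thresh & p < p_thresh
  data.frame(gene = colnames(e)[keep], r = r[keep], p = p[keep],
             row.names = NULL)
}

#' Hypergeometric enrichment of metabolic genes among correlated DEGs
#'
#' Upper-tail probability that the overlap between the correlated DEG set
#' and the metabolite's metabolic gene set is at least as large as
#' observed, drawing `|correlated|` genes without replacement from the
#' universe.
#'
#' @param correlated character vector (correlated DEGs), subset of
#'   `universe`.
#' @param metabolic character vector (metabolic genes), subset of
#'   `universe`.
#' @param universe character vector of all genes on the platform.
#' @return p-value, `P(X >= k)`.
#' @export
hypergeometric_enrichment <- function(correlated, metabolic, universe) {
  if (length(universe) == 0L) stop("empty universe")
  correlated <- intersect(unique(correlated), universe)
  metabolic <- intersect(unique(metabolic), universe)
  k <- length(intersect(correlated, metabolic))
  stats::phyper(k - 1, m = length(metabolic),
                n = length(universe) - length(metabolic),
                k = length(correlated), lower.tail = FALSE)
}

#' Rank-sum enrichment of metabolic-gene p-values
#'
#' One-sided Wilcoxon rank sum test of whether the metabolic target genes'
#' differential-expression p-values are stochastically smaller than those
#' of the other genes in the transcriptome. Uses the exact null
#' distribution when the combined sample size is at most 25 and tie-free,
#' the tie-corrected normal approximation otherwise.
#'
#' @param metabolic_p DE p-values of the metabolic genes.
#' @param other_p DE p-values of the remaining genes.
#' @return one-sided p-value.
#' @export
wilcoxon_enrichment <- function(metabolic_p, other_p) {
  if (length(metabolic_p) == 0L || length(other_p) == 0L)
    stop("both groups must be non-empty")
  combined <- c(metabolic_p, other_p)
  exact <- length(combined) <= 25L && !anyDuplicated(combined)
  suppressWarnings(
    stats::wilcox.test(metabolic_p, other_p, alternative = "less",
                       exact = exact, correct = TRUE)$p.value)
}

#' Metabolite enrichment over a cohort
#'
#' For each candidate metabolite with at least one metabolic gene, runs
#' both enrichment routes: (i) the hypergeometric test on the overlap of
#' its metabolic genes with the DEGs correlated to it, and (ii) the
#' rank-sum generalization on the DE p-values of its metabolic genes
#' versus the rest of the transcriptome. BH correction is applied
#' separately per test family across the candidates; a metabolite is
#' enriched when either q-value falls below `fdr`.
#'
#' @param abund samples x metabolites abundance matrix (e.g. normalized
#'   peak areas, columns named by metabolite).
#' @param expr samples x genes expression matrix.
#' @param de result of [paired_de_test()] on `expr`.
#' @param db a [pathway_db()].
#' @param candidates metabolite ids to test (default: all indexed
#'   metabolites with at least one metabolic gene).
#' @param fdr FDR threshold (default 0.1).
#' @param r_thresh,p_thresh correlation filter, see
#'   [correlate_metabolite_degs()].
#' @param universe gene universe for the hypergeometric test (default all
#'   columns of `expr`).
#' @return data frame of class `metabolite_enrichment`: `metabolite`,
#'   `n_metabolic`, `n_correlated`, `overlap`, `p_hyper`, `q_hyper`,
#'   `p_wilcoxon`, `q_wilcoxon`, `enriched`, plus a `correlations`
#'   attribute (list of per-metabolite retained DEG data frames).
#' @export
enrich_metabolites <- function(abund, expr, de, db, candidates = NULL,
                               fdr = 0.1, r_thresh = 0.5, p_thresh = 0.05,
                               universe = NULL) {
  abund <- as.matrix(abund)
  expr <- as.matrix(expr)
  if (is.null(universe)) universe <- colnames(expr)
  if (is.null(candidates)) candidates <- names(db$metabolite_index)
  candidates <- intersect(candidates, colnames(abund))
  degs <- de$feature_id[de$significant]
  dexpr <- expr[, intersect(degs, colnames(expr)), drop = FALSE]
  rows <- list(); cors <- list()
  for (m in candidates) {
    mg <- suppressWarnings(metabolic_genes_for(m, db))
    mg <- intersect(mg, universe)
    if (length(mg) == 0L) next
    cc <- correlate_metabolite_degs(abund[, m], dexpr,
                                    r_thresh = r_thresh, p_thresh = p_thresh)
    cors[[m]] <- cc
    ph <- hypergeometric_enrichment(cc$gene, mg, universe)
    pv <- de$p[match(universe, de$feature_id)]
    is_mg <- universe %in% mg
    pw <- wilcoxon_enrichment(pv[is_mg], pv[!is_mg])
    rows[[m]] <- data.frame(metabolite = m,
                            n_metabolic = length(mg),
                            n_correlated = nrow(cc),
                            overlap = length(intersect(cc$gene, mg)),
                            p_hyper = ph, p_wilcoxon = pw)
  }
  if (length(rows) == 0L) {
    out <- data.frame(metabolite = character(0), n_metabolic = integer(0),
                      n_correlated = integer(0), overlap = integer(0),
                      p_hyper = numeric(0), q_hyper = numeric(0),
                      p_wilcoxon = numeric(0), q_wilcoxon = numeric(0),
                      enriched = logical(0))
    attr(out, "correlations") <- list()
    class(out) <- c("metabolite_enrichment", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- select_enriched_metabolites(out, fdr = fdr)
  attr(out, "correlations") <- cors
  class(out) <- c("metabolite_enrichment", "data.frame")
  out
}

#' Call enriched metabolites at an FDR threshold
#'
#' Applies BH correction separately to the hypergeometric and rank-sum
#' p-value families across the candidate metabolites and flags a
#' metabolite enriched when either q-value is below `fdr`.
#'
#' @param candidates data frame with `p_hyper` and `p_wilcoxon` columns.
#' @param fdr threshold (default 0.1).
#' @return `candidates` with `q_hyper`, `q_wilcoxon`, `enriched` columns.
#' @export
select_enriched_metabolites <- function(candidates, fdr = 0.1) {
  candidates$q_hyper <- bh_adjust(candidates$p_hyper)
  candidates$q_wilcoxon <- bh_adjust(candidates$p_wilcoxon)
  candidates$enriched <- candidates$q_hyper < fdr |
    candidates$q_wilcoxon < fdr
  candidates
}

#' Overlay miRNA regulators on the metabolic gene set
#'
#' Keeps the significantly differentially expressed miRNAs having at least
#' one validated target inside the metabolic gene set and returns their
#' edges into that set.
#'
#' @param metabolic_genes character vector, the network's metabolic genes.
#' @param targets data frame `mirna_id`, `gene_id`, `support`
#'   (`"validated"`/`"predicted"`).
#' @param demirnas [paired_de_test()] result for the miRNA matrix.
#' @param support which support classes count (default `"validated"`).
#' @param min_targets keep only miRNAs with at least this many metabolic
#'   targets (default 1; the network-reduction rule uses larger values).
#' @return data frame `mirna`, `gene` of retained edges.
#' @export
mirna_overlay <- function(metabolic_genes, targets, demirnas,
                          support = "validated", min_targets = 1) {
  sig <- demirnas$feature_id[demirnas$significant]
  t2 <- targets[targets$support %in% support &
                  targets$mirna_id %in% sig &
                  targets$gene_id %in% metabolic_genes, , drop = FALSE]
  if (nrow(t2) == 0L)
    return(data.frame(mirna = character(0), gene = character(0)))
  deg <- table(t2$mirna_id)
  keep <- names(deg)[deg >= min_targets]
  t2 <- t2[t2$mirna_id %in% keep, , drop = FALSE]
  data.frame(mirna = t2$mirna_id, gene = t2$gene_id, row.names = NULL)
}

#' Topological impact of matched metabolites in a pathway
#'
#' Importance of each metabolite node is its relative centrality
#' (betweenness by default, out-degree optionally) in the pathway's
#' directed metabolite graph, normalized so importances sum to one within
#' the pathway. The pathway impact is the summed importance of the matched
#' metabolites, in `[0, 1]`. When every centrality is zero (e.g. a graph
#' without paths) the importance is uniform and the result is flagged.
#'
#' @param db a [pathway_db()].
#' @param pathway_id pathway to score.
#' @param matched_metabolites character vector of matched metabolite ids.
#' @param centrality `"betweenness"` (default) or `"outdegree"`.
#' @return impact value in `[0, 1]`, with attribute `uniform = TRUE` when
#'   the all-zero-centrality fallback was used.
#' @export
pathway_impact <- function(db, pathway_id, matched_metabolites,
                           centrality = c("betweenness", "outdegree")) {
  stopifnot(inherits(db, "pathway_db"))
  centrality <- match.arg(centrality)
  p <- db$pathways[[pathway_id]]
  if (is.null(p)) stop("unknown pathway: ", pathway_id)
  mets <- p$metabolites
  if (length(mets) == 0L) stop("pathway has no metabolites")
  g <- igraph::graph_from_data_frame(
    as.data.frame(p$edges, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = mets))
  cen <- if (centrality == "betweenness") {
    igraph::betweenness(g, directed = TRUE)
  } else {
    igraph::degree(g, mode = "out")
  }
  uniform <- FALSE
  if (sum(cen) == 0) {
    cen <- rep(1, length(cen))
    names(cen) <- mets
    uniform <- TRUE
  }
  importance <- cen / sum(cen)
  impact <- sum(importance[intersect(matched_metabolites, mets)])
  attr(impact, "uniform") <- uniform
  impact
}
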