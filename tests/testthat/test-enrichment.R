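two_pathway_db <- function() {
  pathway_db(list(
    P1 = list(genes = paste0("g", 1:5), metabolites = c("m1", "m3"),
              edges = rbind(c("m1", "m3"))),
    P2 = list(genes = paste0("g", 4:8), metabolites = c("m2", "m3"),
              edges = NULL)))
}

test_that("metabolic gene sets are unions over the metabolite's pathways", {
  db <- two_pathway_db()
  expect_setequal(metabolic_genes_for("m1", db), paste0("g", 1:5))
  # m3 is in both pathways (5 + 5 genes sharing g4, g5): union of size 8
  expect_setequal(metabolic_genes_for("m3", db), paste0("g", 1:8))
  expect_length(metabolic_genes_for("m3", db), 8)
  expect_warning(out <- metabolic_genes_for("mX", db), "not indexed")
  expect_length(out, 0)
})

test_that("correlation filter applies |r| > 0.5 strictly and p < 0.05", {
  # exact copy: r = 1, retained
  v <- stats::setNames(rnorm(10, 5), paste0("s", 1:10))
  e <- matrix(v, 10, 1, dimnames = list(names(v), "gA"))
  r <- correlate_metabolite_degs(v, e)
  expect_equal(r$gene, "gA"); expect_equal(r$r, 1, tolerance = 1e-12)
  # r exactly 0.5 (integer construction, exact in floating point): dropped
  x <- c(1, 1, 1, 1, -1, -1, -1, -1)
  y <- c(1, 1, 1, -1, -1, 1, -1, -1)
  expect_equal(cor(x, y), 0.5)
  vb <- stats::setNames(x, paste0("s", 1:8))
  eb <- matrix(y, 8, 1, dimnames = list(names(vb), "gB"))
  expect_equal(nrow(correlate_metabolite_degs(vb, eb)), 0)
  # n = 10 at r ~ 0.64: p = 2*pt(-r*sqrt(8)/sqrt(1-r^2), 8) ~ 0.0466 -> retained
  set.seed(6)
  base <- rnorm(10)
  z <- orthogonalize(rnorm(10), base)
  g <- 0.64 * scale(base)[, 1] + 3 * sqrt(1 - 0.64^2) * z
  vc <- stats::setNames(base, paste0("s", 1:10))
  ec <- matrix(g, 10, 1, dimnames = list(names(vc), "gC"))
  rc <- correlate_metabolite_degs(vc, ec)
  expect_equal(cor(base, g), 0.64, tolerance = 1e-10)
  expect_equal(rc$gene, "gC")
  expect_lt(rc$p, 0.05)
  expect_equal(rc$p, 2 * pt(-0.64 * sqrt(8) / sqrt(1 - 0.64^2), 8),
               tolerance = 1e-10)
  expect_error(correlate_metabolite_degs(vc[1:2], ec[1:2, , drop = FALSE]),
               "3 aligned")
})

test_that("hypergeometric enrichment matches enumeration and edge cases", {
  # N=20, K=5, n=4, k=3: 155/4845 by full draw enumeration
  universe <- paste0("g", 1:20)
  metabolic <- paste0("g", 1:5)
  correlated <- c("g1", "g2", "g3", "g6")
  p <- hypergeometric_enrichment(correlated, metabolic, universe)
  draws <- combn(20, 4)
  hits <- colSums(draws <= 5)
  expect_equal(mean(hits >= 3), 155 / 4845, tolerance = 1e-12)
  expect_equal(p, 155 / 4845, tolerance = 1e-12)
  # k = 0: p = 1
  expect_equal(hypergeometric_enrichment("g6", metabolic, universe), 1)
  # k = n = K: single most extreme outcome
  expect_equal(hypergeometric_enrichment(paste0("g", 1:5), metabolic, universe),
               1 / choose(20, 5), tolerance = 1e-12)
  expect_error(hypergeometric_enrichment("a", "a", character(0)), "universe")
})

test_that("rank-sum enrichment is one-sided with exact small-sample p", {
  # 2 vs 3, metabolic strictly smaller: p = 1/C(5,2) = 0.1
  expect_equal(wilcoxon_enrichment(c(0.001, 0.002), c(0.5, 0.6, 0.7)), 0.1,
               tolerance = 1e-12)
  # no shift (identical groups): p near 0.5
  set.seed(1)
  v <- runif(10)
  p_id <- wilcoxon_enrichment(v, v)
  expect_gt(p_id, 0.4)
  expect_lt(p_id, 0.6)
  # wrong direction: p large
  expect_gte(wilcoxon_enrichment(c(0.8, 0.9), c(0.1, 0.2, 0.3)), 0.9)
  expect_error(wilcoxon_enrichment(numeric(0), 0.5), "non-empty")
})

test_that("enrichment calls respect the either-test FDR rule", {
  one <- data.frame(metabolite = "m1", p_hyper = 0.05, p_wilcoxon = 0.9)
  r <- select_enriched_metabolites(one)
  expect_true(r$enriched)            # m = 1 so q = p = 0.05 < 0.1
  all1 <- data.frame(metabolite = paste0("m", 1:5),
                     p_hyper = rep(1, 5), p_wilcoxon = rep(1, 5))
  expect_false(any(select_enriched_metabolites(all1)$enriched))
})

test_that("miRNA overlay gates on DE then on metabolic targets", {
  demir <- data.frame(feature_id = c("mirA", "mirB", "mirC"),
                      significant = c(TRUE, TRUE, FALSE))
  mg <- paste0("g", 1:20)
  targets <- rbind(
    data.frame(mirna_id = "mirA", gene_id = paste0("g", 1:12), support = "validated"),
    data.frame(mirna_id = "mirB", gene_id = paste0("x", 1:5), support = "validated"),
    data.frame(mirna_id = "mirC", gene_id = paste0("g", 1:15), support = "validated"))
  r <- mirna_overlay(mg, targets, demir)
  expect_setequal(unique(r$mirna), "mirA")   # B has no metabolic target, C not DE
  expect_equal(sum(r$mirna == "mirA"), 12)
  # the network-reduction rule drops low-degree miRNAs
  r2 <- mirna_overlay(mg, targets, demir, min_targets = 13)
  expect_equal(nrow(r2), 0)
})

test_that("pathway impact follows relative betweenness on the directed graph", {
  db <- pathway_db(list(P = list(
    genes = "g1", metabolites = c("A", "B", "C"),
    edges = rbind(c("A", "B"), c("B", "C")))))
  expect_equal(as.numeric(pathway_impact(db, "P", "B")), 1.0)
  expect_equal(as.numeric(pathway_impact(db, "P", "A")), 0.0)
  expect_equal(as.numeric(pathway_impact(db, "P", c("A", "B", "C"))), 1.0)
  # out-degree centrality variant: A and B each have out-degree 1
  expect_equal(as.numeric(pathway_impact(db, "P", "A", centrality = "outdegree")),
               0.5)
  # edgeless graph falls back to uniform importance, flagged
  db0 <- pathway_db(list(P = list(genes = "g1",
                                  metabolites = c("A", "B"), edges = NULL)))
  i0 <- pathway_impact(db0, "P", "A")
  expect_equal(as.numeric(i0), 0.5)
  expect_true(attr(i0, "uniform"))
  # monotone in the matched set
  set.seed(2)
  mets <- paste0("M", 1:6)
  eg <- cbind(sample(mets, 8, TRUE), sample(mets, 8, TRUE))
  eg <- eg[eg[, 1] != eg[, 2], , drop = FALSE]
  dbr <- pathway_db(list(P = list(genes = "g", metabolites = mets, edges = eg)))
  prev <- 0
  for (k in 1:6) {
    cur <- as.numeric(pathway_impact(dbr, "P", mets[1:k]))
    expect_gte(cur, prev - 1e-12)
    expect_lte(cur, 1 + 1e-12)
    prev <- cur
  }
})

test_that("enrichment pipeline is invariant to gene and metabolite ordering", {
  co <- generate_cohort(synthetic_config(n_horses = 10, n_metabolites = 10,
    n_genes = 100, n_mirnas = 10, n_pathways = 5, genes_per_pathway = 10,
    n_active_metabolites = 2, n_active_regulators = 0,
    frac_de_genes = 0.1, seed = 42))
  de <- paired_de_test(co$genes, co$metadata)
  e1 <- enrich_metabolites(co$peaks$intensities, co$genes, de, co$pathways)
  gp <- sample(ncol(co$genes)); mp <- sample(ncol(co$peaks$intensities))
  de2 <- paired_de_test(co$genes[, gp], co$metadata)
  e2 <- enrich_metabolites(co$peaks$intensities[, mp], co$genes[, gp],
                           de2, co$pathways)
  m <- match(e1$metabolite, e2$metabolite)
  expect_equal(e1$p_hyper, e2$p_hyper[m], tolerance = 1e-12)
  expect_equal(e1$p_wilcoxon, e2$p_wilcoxon[m], tolerance = 1e-12)
  expect_equal(e1$enriched, e2$enriched[m])
})

test_that("network assembly types nodes, tags evidence, and round-trips", {
  co <- generate_cohort(synthetic_config(seed = 7))
  de_g <- paired_de_test(co$genes, co$metadata)
  de_m <- paired_de_test(co$mirnas, co$metadata)
  enr <- enrich_metabolites(co$peaks$intensities, co$genes, de_g, co$pathways)
  targets <- generate_target_db(co$config, co$truth)
  mg <- unique(unlist(lapply(enr$metabolite[enr$enriched], function(m)
    intersect(suppressWarnings(metabolic_genes_for(m, co$pathways)),
              de_g$feature_id[de_g$significant]))))
  mo <- mirna_overlay(mg, targets, de_m, min_targets = 5)
  tfs <- co$truth$de_genes[1:3]
  net <- assemble_network(enr, co$pathways, de_g, de_m, mirna_edges = mo,
                          tf_list = tfs,
                          metabolite_direction = co$truth$metabolite_direction)
  expect_true(all(net$edges$source %in% net$nodes$id))
  expect_true(all(net$edges$target %in% net$nodes$id))
  expect_false(any(net$edges$source == net$edges$target))
  expect_true(all(net$edges$evidence %in%
                    c("pathway_membership", "correlation", "mirna_target")))
  expect_true(all(net$nodes$kind[net$nodes$id %in% tfs] == "tf"))
  # planted couplings appear among the metabolite-gene edges
  planted <- with(co$truth$metabolite_gene_pairs, paste(metabolite, gene))
  found <- with(net$edges[net$edges$evidence != "mirna_target", ],
                paste(source, target))
  expect_gt(mean(planted %in% found), 0.5)
  # round trip through GraphML preserves structure and attributes
  f <- tempfile(fileext = ".graphml")
  write_network(net, f)
  back <- read_network(f)
  expect_setequal(with(net$edges, paste(source, target, evidence)),
                  with(back$edges, paste(source, target, evidence)))
  nm <- match(net$nodes$id, back$nodes$id)
  expect_equal(net$nodes$kind, back$nodes$kind[nm])
  # empty enrichment gives an empty network
  none <- enr; none$enriched <- FALSE
  net0 <- assemble_network(none, co$pathways, de_g, de_m)
  expect_equal(nrow(net0$nodes), 0)
  expect_equal(nrow(net0$edges), 0)
})

test_that("null enrichment keeps the false-call rate under the FDR bound", {
  calls <- unlist(lapply(1:3, function(s) {
    co <- generate_cohort(null_config(s))
    de <- paired_de_test(co$genes, co$metadata)
    enrich_metabolites(co$peaks$intensities, co$genes, de, co$pathways)$enriched
  }))
  expect_lte(mean(calls), 0.1 + 1.96 * sqrt(0.1 * 0.9 / length(calls)))
})
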