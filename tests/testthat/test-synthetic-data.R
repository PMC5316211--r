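test_that("the generator is bit-identical under a fixed seed", {
  cfg <- synthetic_config(n_horses = 6, n_metabolites = 8, n_genes = 60,
                          n_mirnas = 10, n_pathways = 4, genes_per_pathway = 10,
                          n_active_metabolites = 2, n_active_regulators = 1,
                          seed = 33)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$peaks$intensities, b$peaks$intensities)
  expect_identical(a$genes, b$genes)
  expect_identical(a$mirnas, b$mirnas)
  expect_identical(a$truth, b$truth)
  expect_identical(generate_target_db(cfg, a$truth),
                   generate_target_db(cfg, b$truth))
  # a different seed changes the data
  c2 <- generate_cohort(synthetic_config(n_horses = 6, n_metabolites = 8,
    n_genes = 60, n_mirnas = 10, n_pathways = 4, genes_per_pathway = 10,
    n_active_metabolites = 2, n_active_regulators = 1, seed = 34))
  expect_false(identical(a$genes, c2$genes))
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(n_active_metabolites = 31), "n_metabolites")
  expect_error(synthetic_config(noise_sd = 0), "positive")
  expect_error(synthetic_config(frac_de_genes = 1), "frac_de_genes")
  expect_error(synthetic_config(latent_coupling = 1.2), "latent_coupling")
  expect_error(synthetic_config(n_horses = 0), "at least 1")
  expect_error(synthetic_config(n_genes = 50, n_pathways = 10,
                                genes_per_pathway = 20), "exceed")
})

test_that("ground truth exactly matches the planted structure", {
  co <- generate_cohort(synthetic_config(seed = 5))
  tr <- co$truth
  expect_length(tr$active_metabolites, 5)
  expect_true(all(tr$active_metabolites %in% co$peaks$peak_ids))
  expect_true(all(tr$de_genes %in% colnames(co$genes)))
  expect_true(all(tr$de_mirnas %in% colnames(co$mirnas)))
  expect_true(all(tr$active_regulators %in% tr$de_mirnas))
  # DE genes include every planted coupled gene
  expect_true(all(tr$metabolite_gene_pairs$gene %in% tr$de_genes))
  # every metabolite is indexed in the pathway database
  expect_setequal(names(co$pathways$metabolite_index), co$peaks$peak_ids)
})

test_that("the pure-null generator yields uniform DE p-values", {
  p <- unlist(lapply(1:3, function(s) {
    co <- generate_cohort(null_config(s, n_genes = 400))
    paired_de_test(co$genes, co$metadata)$p
  }))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("planted metabolite-gene couplings hit the target correlation", {
  co <- generate_cohort(synthetic_config(n_horses = 20, latent_coupling = 0.8,
                                         seed = 1))
  pairs <- co$truth$metabolite_gene_pairs
  r <- mapply(function(m, g) cor(co$peaks$intensities[, m], co$genes[, g]),
              pairs$metabolite, pairs$gene)
  expect_lt(abs(mean(abs(r)) - 0.8), 0.1)
})

test_that("planted-pair correlation is monotone in the coupling parameter", {
  grid <- c(0.3, 0.55, 0.8)
  means <- vapply(grid, function(cp) {
    mean(vapply(1:20, function(s) {
      co <- generate_cohort(synthetic_config(n_horses = 10, n_metabolites = 10,
        n_genes = 100, n_mirnas = 5, n_pathways = 5, genes_per_pathway = 10,
        n_active_metabolites = 3, n_active_regulators = 0,
        frac_de_genes = 0.1, latent_coupling = cp, seed = s))
      pairs <- co$truth$metabolite_gene_pairs
      mean(abs(mapply(function(m, g) cor(co$peaks$intensities[, m], co$genes[, g]),
                      pairs$metabolite, pairs$gene)))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("active regulators are differentially co-expressed with their targets", {
  co <- generate_cohort(synthetic_config(seed = 17))
  md <- co$metadata
  i0 <- md$sample_id[md$timepoint == "T0"]
  i1 <- md$sample_id[md$timepoint == "T1"]
  rt <- co$truth$regulator_targets
  r <- rt$regulator[1]
  tg <- rt$gene[rt$regulator == r]
  r1 <- mean(abs(cor(co$mirnas[i1, r], co$genes[i1, tg])))
  r0 <- mean(abs(cor(co$mirnas[i0, r], co$genes[i0, tg])))
  expect_gt(r1, 0.4)
  expect_lt(r0, 0.3)
})

test_that("pathway construction honors size, partition and overlap targets", {
  # single pathway: every metabolite's metabolic-gene set has that size
  cfg1 <- synthetic_config(n_metabolites = 4, n_genes = 10, n_mirnas = 2,
                           n_pathways = 1, genes_per_pathway = 5,
                           n_active_metabolites = 0, n_active_regulators = 0,
                           frac_de_genes = 0, seed = 2)
  db1 <- generate_pathway_db(cfg1)
  for (m in names(db1$metabolite_index))
    expect_length(metabolic_genes_for(m, db1), 5)
  # disjoint pathways partition their genes
  cfg <- synthetic_config(n_metabolites = 10, n_genes = 100, n_mirnas = 2,
                          n_pathways = 5, genes_per_pathway = 10,
                          n_active_metabolites = 0, n_active_regulators = 0,
                          frac_de_genes = 0, seed = 2)
  db <- generate_pathway_db(cfg)
  sets <- lapply(db$pathways, `[[`, "genes")
  expect_equal(sum(lengths(sets)), length(unique(unlist(sets))))
  # overlap parameter targets the mean pairwise Jaccard
  dbo <- generate_pathway_db(cfg, overlap_jaccard = 0.5)
  sets <- lapply(dbo$pathways, `[[`, "genes")
  jac <- combn(length(sets), 2, function(ij) {
    a <- sets[[ij[1]]]; b <- sets[[ij[2]]]
    length(intersect(a, b)) / length(union(a, b))
  })
  expect_lt(abs(mean(jac) - 0.5), 0.1)
})

test_that("target databases plant high-degree regulators plus binomial decoys", {
  cfg <- synthetic_config(seed = 4)
  co <- generate_cohort(cfg)
  # zero decoys: edges are exactly the planted regulator targets
  t0 <- generate_target_db(cfg, co$truth, decoy_rate = 0)
  expect_true(all(t0$mirna_id %in% co$truth$active_regulators))
  expect_true(all(t0$gene_id %in% co$truth$metabolite_gene_pairs$gene))
  deg <- table(t0$mirna_id)
  expect_true(all(deg >= 10))
  expect_length(deg, length(co$truth$active_regulators))
  # decoy count follows the binomial: rate 0.1 over 10 x 100 = 1000 pairs
  cfg2 <- synthetic_config(n_horses = 5, n_metabolites = 5, n_genes = 100,
                           n_mirnas = 10, n_pathways = 5, genes_per_pathway = 10,
                           n_active_metabolites = 0, n_active_regulators = 0,
                           frac_de_genes = 0, seed = 9)
  co2 <- generate_cohort(cfg2)
  td <- generate_target_db(cfg2, co2$truth, decoy_rate = 0.1)
  expect_gte(nrow(td), qbinom(0.005, 1000, 0.1))
  expect_lte(nrow(td), qbinom(0.995, 1000, 0.1))
})
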