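test_that("zero-noise forced shapes realize the configured effects exactly", {
  cfg <- sim_config(5, noise_cv = 0, responsive_effect_log2 = 2,
                    force_category = "MKP1_independent", force_archetype = 3,
                    seed = 1)
  sim <- simulate_expression(cfg)
  e <- sim$expression
  for (gt in c("Ws", "mkp1", "mkp1_mpk6")) {
    m <- tapply(e$fpkm[e$genotype == gt], list(e$gene_id[e$genotype == gt],
                                               e$timepoint_min[e$genotype == gt]),
                mean)
    ratios <- log2(m / m[, "0"])
    expect_equal(unname(ratios[, "30"]), rep(2, 5), tolerance = 1e-12)
    expect_equal(unname(ratios[, "90"]), rep(2, 5), tolerance = 1e-12)
  }
})

test_that("planted epistasis structure holds exactly at zero noise", {
  for (cat in c("MKP1_MPK6_dependent", "MKP1_dep_MPK6_indep", "partial_MPK6")) {
    cfg <- sim_config(3, noise_cv = 0, force_category = cat,
                      force_archetype = 3, seed = 2)
    e <- simulate_expression(cfg)$expression
    m30 <- tapply(e$fpkm[e$timepoint_min == 30],
                  list(e$gene_id[e$timepoint_min == 30],
                       e$genotype[e$timepoint_min == 30]), mean)
    d_mut <- log2(m30[, "mkp1"] / m30[, "Ws"])
    d_dbl <- log2(m30[, "mkp1_mpk6"] / m30[, "Ws"])
    expect_equal(unname(d_mut), rep(1, 3), tolerance = 1e-12)
    expected_dbl <- switch(cat, MKP1_MPK6_dependent = 0,
                           MKP1_dep_MPK6_indep = 1, partial_MPK6 = 0.5)
    expect_equal(unname(d_dbl), rep(expected_dbl, 3), tolerance = 1e-12)
  }
})

test_that("same seed gives bit-identical output, different seed differs", {
  cfg <- sim_config(50, seed = 7)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a, b)
  c_ <- simulate_expression(sim_config(50, seed = 8))
  expect_false(identical(a$expression$fpkm, c_$expression$fpkm))
})

test_that("category proportions follow the configured mix", {
  counts <- 0
  for (s in 1:50) {
    tr <- simulate_expression(sim_config(200, seed = s))$truth
    counts <- counts + table(factor(tr$category,
                                    levels = names(sim_config(1)$category_mix)))
  }
  p <- chisq.test(counts, p = sim_config(1)$category_mix)$p.value
  expect_gt(p, 0.001)
})

test_that("sim_config rejects invalid worlds", {
  expect_error(sim_config(0), class = "elicitr_input_error")
  expect_error(sim_config(10, n_replicates = 1), class = "elicitr_input_error")
  expect_error(sim_config(10, category_mix = c(nonresponsive = 1)),
               class = "elicitr_input_error")
  expect_error(sim_config(10, force_archetype = 9),
               class = "elicitr_input_error")
  bad_mix <- c(nonresponsive = 0.5, MKP1_independent = 0.4,
               MKP1_MPK6_dependent = 0.04, MKP1_dep_MPK6_indep = 0.04,
               partial_MPK6 = 0.04)
  expect_error(sim_config(10, category_mix = bad_mix),
               class = "elicitr_input_error")
})

test_that("planted_calls marks responsiveness exactly where shapes are non-zero", {
  cfg <- sim_config(400, seed = 3)
  tr <- simulate_expression(cfg)$truth
  pc <- planted_calls(tr)
  shapes <- archetype_shapes()
  # cluster 1 genes respond at 30 only; cluster 2 at 90 only
  c1 <- tr$gene_id[!is.na(tr$archetype) & tr$archetype == 1]
  c2 <- tr$gene_id[!is.na(tr$archetype) & tr$archetype == 2]
  expect_true(all(pc$responsive[pc$gene_id %in% c1 & pc$timepoint_min == 30]))
  expect_false(any(pc$responsive[pc$gene_id %in% c1 & pc$timepoint_min == 90]))
  expect_false(any(pc$responsive[pc$gene_id %in% c2 & pc$timepoint_min == 30]))
  expect_true(all(pc$responsive[pc$gene_id %in% c2 & pc$timepoint_min == 90]))
  # repressed archetypes carry the repressed direction
  c7 <- tr$gene_id[!is.na(tr$archetype) & tr$archetype == 7]
  expect_true(all(pc$direction[pc$gene_id %in% c7 & pc$timepoint_min == 90] ==
                    "repressed"))
})

test_that("annotation simulator plants enrichment and respects edge cases", {
  genes <- sprintf("g%03d", 1:500)
  ann <- simulate_annotations(genes, 20, 2, study_genes = genes[1:60],
                              seed = 5)
  expect_setequal(names(ann$term_map), c("gene_id", "term_id"))
  expect_equal(sum(ann$truth$enriched), 2)
  # enriched terms over-represent the study set
  for (tm in ann$truth$term_id[ann$truth$enriched]) {
    members <- ann$term_map$gene_id[ann$term_map$term_id == tm]
    rate_study <- mean(genes[1:60] %in% members)
    rate_rest <- mean(genes[61:500] %in% members)
    expect_gt(rate_study, rate_rest)
  }
  expect_error(simulate_annotations(character(), 5),
               class = "elicitr_input_error")
  expect_error(simulate_annotations(genes, 5, 6, genes[1:10]),
               class = "elicitr_input_error")
})

test_that("qPCR curve simulator validates physics and is deterministic", {
  expect_error(simulate_qpcr(1, efficiency = 1, true_quantity = 1e-5),
               class = "elicitr_input_error")
  expect_error(simulate_qpcr(1, efficiency = 2.1, true_quantity = 1e-5),
               class = "elicitr_input_error")
  expect_error(simulate_qpcr(1, efficiency = 2, true_quantity = 1e-5,
                             cycles = 20), class = "elicitr_input_error")
  a <- simulate_qpcr(3, 1.9, 1e-5, seed = 11)
  b <- simulate_qpcr(3, 1.9, 1e-5, seed = 11)
  expect_identical(a, b)
  # curve saturates at the plateau and starts near baseline
  f <- a$curves$fluorescence[a$curves$reaction_id == "R001"]
  expect_lt(f[1], 2)
  expect_gt(max(f), 90)
  expect_lt(max(f), 105)
})
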