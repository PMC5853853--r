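test_that("responsiveness thresholds are inclusive and union over genotypes", {
  # boundary: |lfc| = 1.0 and q = 0.01 exactly qualify
  d <- gene_diffs("g1", list(Ws_30 = c(1.0, 0.01)))
  calls <- classify_genes(d)
  c30 <- calls[calls$timepoint_min == 30, ]
  expect_true(c30$responsive)
  expect_equal(c30$direction, "induced")
  expect_equal(c30$category, "MKP1_independent")

  # single-mutant-only qualification, repressed
  d <- gene_diffs("g1", list(mkp1_30 = c(-1.4, 0.001)))
  c30 <- classify_genes(d)
  c30 <- c30[c30$timepoint_min == 30, ]
  expect_true(c30$responsive)
  expect_equal(c30$direction, "repressed")

  # just under either gate fails
  d <- gene_diffs("g1", list(Ws_30 = c(0.999, 0.01)))
  expect_false(classify_genes(d)$responsive[1])
  d <- gene_diffs("g1", list(Ws_30 = c(1.0, 0.0101)))
  expect_false(classify_genes(d)$responsive[1])
})

test_that("direction precedence and conflict counting", {
  d <- gene_diffs("g1", list(Ws_30 = c(1.2, 0.001), mkp1_30 = c(-1.5, 0.001)))
  calls <- classify_genes(d)
  expect_equal(calls$direction[calls$timepoint_min == 30], "induced")
  expect_equal(attr(calls, "conflicts"), 1L)
})

test_that("MKP1 dependence gate: inclusive fold and q, independence by subtraction", {
  base <- list(Ws_30 = c(2, 0.001))
  # fold exactly 1.5 at q 0.005: dependent
  d <- gene_diffs("g1", c(base, list(dep_30 = c(log2(1.5), 0.005))))
  expect_equal(classify_genes(d)$category[1], "MKP1_dep_partial_MPK6")
  # strong fold but q = 0.5: independent (significance gate)
  d <- gene_diffs("g1", c(base, list(dep_30 = c(log2(3), 0.5))))
  expect_equal(classify_genes(d)$category[1], "MKP1_independent")
  # hypo-accumulation counts too (fold in either direction)
  d <- gene_diffs("g1", c(base, list(dep_30 = c(-log2(2), 0.001))))
  expect_true(classify_genes(d)$category[1] != "MKP1_independent")
})

test_that("MPK6 subdivision decision table", {
  base <- list(Ws_30 = c(2, 0.001), dep_30 = c(1, 0.001))
  case <- function(qa, qb) {
    d <- gene_diffs("g1", c(base, list(mpk6a_30 = c(0.5, qa),
                                       mpk6b_30 = c(0.5, qb))))
    classify_genes(d)$category[1]
  }
  expect_equal(case(0.001, 0.5), "MKP1_MPK6_dependent")
  expect_equal(case(0.5, 0.001), "MKP1_dep_MPK6_indep")
  expect_equal(case(0.001, 0.001), "MKP1_dep_partial_MPK6")
  expect_equal(case(0.5, 0.5), "MKP1_dep_partial_MPK6")
  # boundary: q = 0.01 counts as significant in the subdivision gates
  expect_equal(case(0.01, 0.5), "MKP1_MPK6_dependent")
})

test_that("timepoint labels are independent (category switching allowed)", {
  d <- gene_diffs("g1", list(Ws_30 = c(2, 0.001), Ws_90 = c(2, 0.001),
                             dep_90 = c(1, 0.001), mpk6b_90 = c(1, 0.001)))
  calls <- classify_genes(d)
  expect_equal(calls$category[calls$timepoint_min == 30], "MKP1_independent")
  expect_equal(calls$category[calls$timepoint_min == 90],
               "MKP1_dep_MPK6_indep")
})

test_that("missing contrasts degrade gracefully with gap accounting", {
  d <- gene_diffs("g1", list(Ws_30 = c(2, 0.001)))
  d <- d[!(d$sample_1 == "Ws_0" & d$sample_2 == "Ws_90") &
           !(d$sample_1 == "mkp1_0" & d$sample_2 == "mkp1_90"), ]
  calls <- classify_genes(d)
  expect_false(calls$responsive[calls$timepoint_min == 90])
  expect_equal(attr(calls, "gaps"), 1L)
  # non-OK records are unusable for decisions
  d2 <- gene_diffs("g1", list(Ws_30 = c(2, 0.001)))
  d2$status[d2$sample_1 == "Ws_0" & d2$sample_2 == "Ws_30"] <- "NOTEST"
  expect_false(classify_genes(d2)$responsive[1])
})

test_that("baseline genotype differences are flagged, not excluded", {
  d <- gene_diffs("g1", list(Ws_30 = c(2, 0.001), base_mkp1 = c(1, 0.001)))
  calls <- classify_genes(d)
  expect_true(all(calls$baseline_diff))
  expect_true(calls$responsive[calls$timepoint_min == 30])
})

test_that("vectorized classifier agrees with the naive predicate oracle", {
  diffs <- random_diffs(300, seed = 77)
  got <- classify_genes(diffs)
  want <- classify_oracle(diffs)
  got <- got[order(got$timepoint_min, got$gene_id), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got[names(want)], want)
})

test_that("categories partition the responsive set; monotone in dep fold", {
  diffs <- random_diffs(500, seed = 5)
  calls <- classify_genes(diffs)
  dep_cats <- c("MKP1_independent", "MKP1_MPK6_dependent",
                "MKP1_dep_MPK6_indep", "MKP1_dep_partial_MPK6")
  for (t in c(30, 90)) {
    ct <- calls[calls$timepoint_min == t, ]
    expect_true(all(ct$category[ct$responsive] %in% dep_cats))
    expect_true(all(ct$category[!ct$responsive] == "not_responsive"))
    expect_true(all(ct$direction[!ct$responsive] == "none"))
    expect_true(all(ct$direction[ct$responsive] %in% c("induced", "repressed")))
  }
  dep_count <- function(fold) {
    th <- call_thresholds(dep_fold_min = fold)
    sum(classify_genes(diffs, th)$category %in% dep_cats[-1])
  }
  counts <- vapply(c(1.2, 1.5, 2, 3, 5), dep_count, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("classifier recovers planted categories on synthetic data", {
  cfg <- sim_config(2000, seed = 42)
  sim <- simulate_expression(cfg)
  calls <- classify_genes(test_all_contrasts(sim$expression))
  truthc <- planted_calls(sim$truth)
  m <- merge(calls, truthc, by = c("gene_id", "timepoint_min"),
             suffixes = c("", ".planted"))
  # overall category recovery
  expect_gte(mean(m$category == m$category.planted), 0.90)
  # responsive set sensitivity and specificity
  expect_gte(mean(m$responsive[m$responsive.planted]), 0.95)
  expect_gte(mean(!m$responsive[!m$responsive.planted]), 0.95)
})

test_that("planted dependence at 2-fold is flagged dependent", {
  # dependence-only recovery on a fixture where every gene carries the
  # mutant offset; BH within the contrast then operates at full signal
  cfg <- sim_config(2000, seed = 43, force_category = "MKP1_dep_MPK6_indep",
                    force_archetype = 3)
  sim <- simulate_expression(cfg)
  calls <- classify_genes(test_all_contrasts(sim$expression))
  dep <- calls$category %in% c("MKP1_MPK6_dependent", "MKP1_dep_MPK6_indep",
                               "MKP1_dep_partial_MPK6")
  expect_gte(mean(dep), 0.90)
})

test_that("summary arithmetic reproduces the printed percentage style", {
  expect_equal(percent_of(180, 220), 82)
  expect_equal(percent_of(40, 220), 18)
  expect_equal(percent_of(262, 2114), 12)
  expect_true(is.na(percent_of(0, 0)))

  # zero denominators flow through summarize_categories without division
  calls <- data.frame(gene_id = "g1", timepoint_min = 30, responsive = FALSE,
                      direction = "none", category = "not_responsive")
  s <- summarize_categories(calls)
  expect_true(all(is.na(s$pct_int[s$denominator == 0])))
  expect_false(any(is.infinite(s$pct_int), na.rm = TRUE))
})
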