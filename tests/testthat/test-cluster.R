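test_that("profile enumeration matches the (2c+1)^(T-1) oracle", {
  pr <- enumerate_profiles(3, 2, 50)
  expect_equal(nrow(pr$levels), 25)
  expect_equal(pr$levels[, 1], rep(0, 25))
  expect_true(all(abs(pr$steps) <= 2))
  expect_false(any(duplicated(pr$levels)))

  # T=2, c=1: down, flat, up
  pr2 <- enumerate_profiles(2, 1, 50)
  expect_equal(nrow(pr2$levels), 3)
  expect_equal(sort(pr2$levels[, 2]), c(-1, 0, 1))
})

test_that("greedy max-min selection is deterministic and diverse", {
  a <- enumerate_profiles(3, 2, 8)
  b <- enumerate_profiles(3, 2, 8)
  expect_identical(a, b)
  expect_equal(nrow(a$levels), 8)
  # no two selected profiles are proportional (distance 0)
  cors <- elicitR:::safe_cor_matrix(a$levels, a$levels)
  diag(cors) <- 0
  expect_lt(max(cors), 1 - 1e-9)
})

test_that("archetype decision table partitions the 24 non-flat profiles", {
  pr <- enumerate_profiles(3, 2, 50)
  arch <- group_archetypes(pr$levels)
  flat <- apply(pr$levels, 1, function(v) all(v == 0))
  expect_equal(sum(flat), 1)
  expect_true(all(is.na(arch[flat])))
  expect_true(all(arch[!flat] %in% 1:8))
  # exhaustive group sizes from the step enumeration
  expect_equal(as.vector(table(arch[!flat])), c(4, 2, 2, 4, 4, 2, 2, 4))
  # worked examples
  expect_equal(group_archetypes(c(0, 2, 0)), 1L)
  expect_equal(group_archetypes(c(0, 0, -2)), 7L)
  expect_equal(group_archetypes(c(0, 1, 1)), 3L)
  expect_equal(group_archetypes(c(0, 1, 2)), 4L)
})

test_that("assignment follows shape, excludes flat and ambiguous genes", {
  pr <- enumerate_profiles(3, 2, 50)
  ratios <- rbind(g1 = c(0, 2, 2),      # sustained induced
                  g2 = c(0, 0, 0),      # flat: unassigned
                  g3 = c(0, -1.8, 0.1)) # transient repressed
  asg <- assign_profiles(ratios, pr)
  expect_equal(asg$archetype[1], 3L)
  expect_true(is.na(asg$profile_id[2]))
  expect_equal(asg$archetype[3], 5L)
  # proportional-profile ties resolve within the shared archetype
  expect_equal(asg$profile_id[1], pr$profile_id[which(
    apply(pr$levels, 1, function(v) all(v == c(0, 1, 1))))])
})

test_that("assignment agrees with a brute-force argmax oracle", {
  set.seed(8)
  pr <- enumerate_profiles(3, 2, 50)
  ratios <- cbind(0, matrix(rnorm(2000, 0, 1.5), ncol = 2))
  rownames(ratios) <- sprintf("g%04d", seq_len(nrow(ratios)))
  asg <- assign_profiles(ratios, pr)
  arch <- group_archetypes(pr$levels)
  for (i in seq_len(nrow(ratios))) {
    cors <- suppressWarnings(
      apply(pr$levels, 1, function(p) stats::cor(ratios[i, ], p)))
    cors[is.na(cors)] <- -Inf
    best <- max(cors)
    tied <- which(cors >= best - 1e-9)
    a <- unique(arch[tied])
    if (length(a) != 1 || any(is.na(a))) {
      expect_true(is.na(asg$profile_id[i]))
    } else {
      expect_equal(asg$archetype[i], a)
      expect_equal(asg$score[i], best, tolerance = 1e-9)
    }
  }
})

test_that("negating every ratio vector mirrors the archetypes exactly", {
  set.seed(9)
  pr <- enumerate_profiles(3, 2, 50)
  ratios <- cbind(0, matrix(rnorm(1000, 0, 2), ncol = 2))
  rownames(ratios) <- sprintf("g%04d", seq_len(nrow(ratios)))
  a <- assign_profiles(ratios, pr)$archetype
  b <- assign_profiles(-ratios, pr)$archetype
  mirror <- c(5L, 7L, 6L, 8L, 1L, 3L, 2L, 4L)
  expect_identical(b, ifelse(is.na(a), NA_integer_, mirror[a]))
})

test_that("planted archetypes are recovered at noise_cv 0.1", {
  cfg <- sim_config(1200, noise_cv = 0.1, seed = 21)
  sim <- simulate_expression(cfg)
  resp <- sim$truth$gene_id[sim$truth$category != "nonresponsive"]
  ratios <- temporal_ratios(sim$expression, resp)
  asg <- assign_profiles(ratios, enumerate_profiles(3, 2, 50))
  planted <- sim$truth$archetype[match(asg$gene_id, sim$truth$gene_id)]
  hit <- !is.na(asg$archetype) & asg$archetype == planted
  expect_gte(mean(hit), 0.95)
})

test_that("profile significance: planted profile is the minimum p", {
  pr <- enumerate_profiles(3, 2, 50)
  set.seed(3)
  ratios <- cbind(0, 2 + rnorm(80, 0, 0.05), 2 + rnorm(80, 0, 0.05))
  rownames(ratios) <- sprintf("g%03d", 1:80)
  ps <- profile_significance(ratios, pr)
  target <- which(apply(pr$levels, 1, function(v) all(v == c(0, 1, 1))))
  expect_equal(which.min(ps$p_value), target)
  expect_lt(ps$q_value[target], 0.05)
})

test_that("profile significance: flat input yields zero expectations", {
  pr <- enumerate_profiles(3, 2, 50)
  ratios <- matrix(0, 10, 3, dimnames = list(sprintf("g%02d", 1:10), NULL))
  ps <- profile_significance(ratios, pr)
  expect_true(all(ps$observed == 0))
  expect_true(all(ps$expected == 0))
  expect_true(all(ps$p_value == 1))
})

test_that("profile significance controls type-I error on random input", {
  pr <- enumerate_profiles(3, 2, 50)
  any_sig <- vapply(1:200, function(s) {
    set.seed(30000 + s)
    ratios <- cbind(0, matrix(rnorm(80, 0, 1), ncol = 2))
    rownames(ratios) <- sprintf("g%02d", 1:40)
    any(profile_significance(ratios, pr)$q_value <= 0.05)
  }, TRUE)
  expect_lte(mean(any_sig), 0.05)
})

test_that("temporal ratios are referenced to the first timepoint", {
  sim <- simulate_expression(sim_config(20, noise_cv = 0, seed = 2,
                                        force_category = "MKP1_independent",
                                        force_archetype = 4))
  r <- temporal_ratios(sim$expression)
  expect_true(all(r[, 1] == 0))
  # amplified shape doubles its log2 ratio between 30 and 90 min (up to
  # pseudocount shrinkage)
  expect_true(all(r[, 3] > r[, 2]))
  expect_error(temporal_ratios(sim$expression, genotype = "nope"),
               class = "elicitr_input_error")
})
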