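test_that("raw AI is left minus right with exact antisymmetry", {
  l <- matrix(c(0.30, 0.1, -0.2, 0.5), 2)
  r <- matrix(c(0.10, 0.1, 0.1, 0.5), 2)
  ai <- asymmetry_index(l, r)
  expect_equal(ai[1, 1], 0.20)
  expect_equal(asymmetry_index(l, l), matrix(0, 2, 2))
  expect_equal(asymmetry_index(r, l), -ai)
  expect_error(asymmetry_index(l, r[1, , drop = FALSE]), "shape")
})

test_that("normalized AI follows the shifted ratio definition", {
  expect_equal(normalized_asymmetry_index(3, 1, shift = 0), 0.5)
  expect_equal(normalized_asymmetry_index(2, 2, shift = 0), 0)
  expect_error(normalized_asymmetry_index(-3, 1, shift = 0), "shift policy")
  # automatic shift renders everything positive
  set.seed(1)
  l <- matrix(rnorm(40), 8); r <- matrix(rnorm(40), 8)
  nai <- normalized_asymmetry_index(l, r)
  expect_true(all(is.finite(nai)))
  s <- ai_shift_constant(l, r)
  expect_true(all(l + s > 0) && all(r + s > 0))
})

test_that("group statistics satisfy the t = d * sqrt(n) identity", {
  set.seed(2)
  ai <- matrix(rnorm(60 * 25, mean = 0.1), 60)
  st <- group_asymmetry_stats(ai)
  expect_lt(max(abs(st$t - st$cohens_d * sqrt(60))), 1e-10)
  expect_equal(unique(st$df), 59L)
  expect_true(all(st$p_fdr >= st$p))
  # a 1014-subject stack reports df = 1013
  big <- matrix(rnorm(1014 * 3), 1014)
  expect_equal(unique(group_asymmetry_stats(big)$df), 1013L)
})

test_that("one-sample t and p agree with stats::t.test", {
  set.seed(3)
  ai <- matrix(rnorm(20 * 6, mean = 0.3), 20)
  st <- group_asymmetry_stats(ai)
  for (j in 1:6) {
    tt <- t.test(ai[, j])
    expect_equal(st$t[j], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(st$p[j], tt$p.value, tolerance = 1e-12)
  }
})

test_that("BH adjustment equals the brute-force step-up computation", {
  p <- c(0.001, 0.01, 0.02, 0.04, 0.2)
  ref <- oracle_bh(p)
  expect_equal(ref, c(0.005, 0.025, 1 / 30, 0.05, 0.2), tolerance = 1e-12)
  # the pipeline's adjusted values use the same step-up rule
  set.seed(4)
  ai <- matrix(rnorm(12 * 40, mean = 0.05), 12)
  st <- group_asymmetry_stats(ai)
  expect_equal(st$p_fdr, oracle_bh(st$p), tolerance = 1e-12)
  # monotone transform of raw p within scope
  ord <- order(st$p)
  expect_true(all(diff(st$p_fdr[ord]) >= -1e-15))
})

test_that("zero-variance parcels are flagged NA with a warning", {
  ai <- cbind(rnorm(10), rep(0.2, 10))
  expect_warning(st <- group_asymmetry_stats(ai), "zero-variance")
  expect_true(is.na(st$cohens_d[2]))
  expect_true(is.na(st$t[2]))
})

test_that("group statistics are antisymmetric under hemisphere relabeling", {
  set.seed(5)
  ai <- matrix(rnorm(30 * 10, mean = 0.2), 30)
  a <- group_asymmetry_stats(ai)
  b <- group_asymmetry_stats(-ai)
  expect_equal(b$mean_ai, -a$mean_ai)
  expect_equal(b$t, -a$t)
  expect_equal(b$cohens_d, -a$cohens_d)
  expect_equal(b$p, a$p)
})

test_that("network summaries aggregate then test across subjects", {
  set.seed(6)
  ai <- matrix(rnorm(40 * 8, mean = 0.1), 40)
  one <- network_summary(ai, rep("all", 8))
  glob <- group_asymmetry_stats(matrix(rowMeans(ai), 40))
  expect_equal(one$mean_ai, glob$mean_ai)
  expect_equal(one$t, glob$t)
  # two opposite networks give +a and -a means
  a <- 0.4
  ai2 <- cbind(matrix(a, 20, 3), matrix(-a, 20, 3)) +
    matrix(rnorm(120, sd = 1e-9), 20)
  two <- network_summary(ai2, rep(c("left_net", "right_net"), each = 3))
  expect_equal(sort(two$mean_ai), sort(c(-a, a)), tolerance = 1e-8)
  # ranked from leftward to rightward dominance
  expect_equal(two$parcel[1], "left_net")
  expect_error(network_summary(ai, rep("x", 3)), "label")
  expect_error(network_summary(ai, c(rep("x", 7), NA)), "[Uu]nlabeled")
})

test_that("a network concentrating the asymmetry field has the largest t", {
  set.seed(7)
  nets <- rep(paste0("N", 1:4), each = 10)
  delta <- ifelse(nets == "N3", 1, 0)
  ai <- t(replicate(50, 0.3 * delta + rnorm(40, sd = 0.5)))
  ns <- network_summary(ai, nets)
  expect_equal(ns$parcel[which.max(abs(ns$t))], "N3")
})
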