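test_that("row sparsification keeps the top entries with deterministic ties", {
  set.seed(1)
  m <- matrix(rnorm(36), 6)
  sp <- sparsify_rows(m, 0.5)
  expect_equal(sp, oracle_sparsify(m, 3))
  # density 1 is the identity
  expect_identical(sparsify_rows(m, 1), m)
  # 180 parcels at 10% leaves exactly 18 entries per row
  big <- matrix(rnorm(180 * 180), 180)
  expect_equal(unname(rowSums(sparsify_rows(big, 0.10) != 0)),
               rep(18, 180))
  # ties break toward the lower column index
  tied <- matrix(c(1, 1, 1, 0.5), 1, 4)
  tied <- rbind(tied, tied, tied, tied)
  sp2 <- sparsify_rows(tied, 0.5)
  expect_equal(sp2[1, ], c(1, 1, 0, 0))
  expect_error(sparsify_rows(matrix(1, 2, 3), 0.5), "square")
})

test_that("normalized-angle affinity maps geometry into [0, 1]", {
  rows <- rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0))
  aff <- normalized_angle_affinity(rows)
  expect_equal(aff[1, 2], 1)            # identical rows
  expect_equal(aff[1, 3], 0.5)          # orthogonal rows
  expect_equal(aff[1, 4], 0)            # antiparallel rows
  expect_equal(aff, t(aff))
  expect_equal(diag(aff), rep(1, 4))
  expect_error(normalized_angle_affinity(rbind(c(1, 1), c(0, 0))),
               "all-zero.*2")
})

test_that("diffusion embedding matches the dense Markov-operator oracle", {
  set.seed(7)
  cfg <- embedding_config(n_components = 5)
  for (i in 1:50) {
    w <- normalized_angle_affinity(matrix(rnorm(30 * 30), 30))
    gs <- diffusion_embedding(w, cfg)
    ora <- oracle_diffusion(w, alpha = 0.5, k = 5)
    for (c in 1:5)
      expect_gt(abs(cor(gs$scores[, c], ora[, c])), 0.999)
  }
})

test_that("embedding spectra are ordered with valid variance fractions", {
  set.seed(8)
  w <- normalized_angle_affinity(matrix(rnorm(40 * 40), 40))
  gs <- diffusion_embedding(w, embedding_config())
  expect_true(all(diff(gs$eigenvalues) <= 1e-12))
  expect_true(all(gs$eigenvalues >= 0))
  expect_true(all(gs$variance_explained >= 0))
  expect_true(all(diff(gs$variance_explained) <= 1e-12))
  expect_lte(sum(gs$variance_explained), 1 + 1e-12)
})

test_that("the first gradient separates a two-block affinity", {
  p <- 20
  w <- matrix(0.02, p, p)
  w[1:10, 1:10] <- 1
  w[11:20, 11:20] <- 1
  diag(w) <- 1
  gs <- diffusion_embedding(w, embedding_config(n_components = 3))
  s1 <- sign(gs$scores[1:10, 1])
  s2 <- sign(gs$scores[11:20, 1])
  expect_true(all(s1 == s1[1]))
  expect_true(all(s2 == -s1[1]))
})

test_that("disconnected affinity graphs are rejected with advice", {
  w <- diag(4)
  expect_error(diffusion_embedding(w, embedding_config()), "disconnected")
})

test_that("embedding is equivariant to parcel permutation", {
  set.seed(9)
  w <- normalized_angle_affinity(matrix(rnorm(25 * 25), 25))
  gs <- diffusion_embedding(w, embedding_config(n_components = 4))
  perm <- sample(25)
  gsp <- diffusion_embedding(w[perm, perm],
                             embedding_config(n_components = 4))
  for (c in 1:4) {
    agreement <- abs(cor(gsp$scores[, c], gs$scores[perm, c]))
    expect_gt(agreement, 1 - 1e-9)
  }
})

test_that("Procrustes alignment recovers orthogonal transforms exactly", {
  set.seed(10)
  tpl <- matrix(rnorm(30 * 6), 30)
  # identity
  self <- procrustes_align(tpl, tpl)
  expect_lt(self$procrustes_residual, 1e-10)
  expect_equal(self$rotation, diag(6), tolerance = 1e-10)
  # single-column reflection
  refl <- tpl; refl[, 3] <- -refl[, 3]
  expect_lt(procrustes_align(refl, tpl)$procrustes_residual, 1e-10)
  # random orthogonal transforms, reflections included
  for (i in 1:25) {
    r0 <- random_orthogonal(6)
    out <- procrustes_align(tpl %*% r0, tpl)
    expect_lt(sqrt(sum((out$scores - tpl)^2)), 1e-8)
  }
  expect_error(procrustes_align(tpl[, 1:3], tpl), "shape")
})

test_that("template orientation follows the anchor and flips with it", {
  set.seed(11)
  co <- make_timeseries_cohort(tiny_cohort_spec(seed = 11))
  fc <- subject_connectome(co, co$pedigree$subject_id[1])
  cfg <- embedding_config(row_density_kept = 0.4, n_components = 4)
  anchor <- co$geometry$latent
  t1 <- build_template(fc$ll, cfg, anchor = anchor)
  t2 <- build_template(fc$ll, cfg, anchor = anchor)
  expect_identical(t1$scores, t2$scores)
  t3 <- build_template(fc$ll, cfg, anchor = -anchor)
  expect_equal(abs(t3$scores), abs(t1$scores), tolerance = 1e-12)
  flipped <- vapply(seq_len(ncol(t1$scores)), function(c)
    isTRUE(all.equal(t3$scores[, c], -t1$scores[, c])) ||
      isTRUE(all.equal(t3$scores[, c], t1$scores[, c])), TRUE)
  expect_true(all(flipped))
  # every retained component correlates nonnegatively with its anchor
  for (c in seq_len(ncol(t1$scores)))
    expect_gte(cor(t1$scores[, c], anchor) + 1e-12, 0)
})

test_that("a mirror-symmetric subject has identical LL and RR gradients", {
  set.seed(12)
  ts <- matrix(rnorm(20 * 120), 20)
  fc <- pearson_fisher_fc(ts, ts)
  cfg <- embedding_config(row_density_kept = 0.4, n_components = 4)
  tpl <- build_template(fc$ll, cfg)
  modes <- embed_all_modes(fc, tpl, cfg)
  expect_lt(max(abs(modes$LL$scores - modes$RR$scores)), 1e-6)
  # RL is definitionally the embedding of lr transposed
  direct <- procrustes_align(
    hemigrad:::mode_gradients(t(fc$lr), cfg), tpl)
  expect_equal(modes$RL$scores, direct$scores)
})

test_that("joint embedding respects mirror symmetry and hemisphere swaps", {
  set.seed(13)
  ts <- matrix(rnorm(16 * 150), 16)
  fc_sym <- pearson_fisher_fc(ts, ts)
  cfg <- embedding_config(row_density_kept = 0.5, n_components = 3)
  gs <- embed_joint(fc_sym, cfg)
  p <- 16
  # homologous rows coincide on the principal axis (the clamped
  # self-correlation diagonal of lr/rl leaves a small residual split)
  expect_gt(cor(gs$scores[1:p, 1], gs$scores[p + 1:p, 1]), 0.99)
  hom_diff_g1 <- gs$scores[1:p, 1] - gs$scores[p + 1:p, 1]
  expect_lt(max(abs(hom_diff_g1)) / stats::sd(gs$scores[1:p, 1]), 0.1)

  # swapping hemispheres negates the joint asymmetry exactly
  ts2 <- ts + matrix(rnorm(16 * 150, sd = 0.5), 16)
  fc <- pearson_fisher_fc(ts, ts2)
  joint <- rbind(cbind(fc$ll, fc$lr), cbind(fc$rl, fc$rr))
  tpl <- build_template(joint, cfg)
  a <- procrustes_align(hemigrad:::mode_gradients(joint, cfg), tpl)
  swapped <- rbind(cbind(fc$rr, fc$rl), cbind(fc$lr, fc$ll))
  b <- procrustes_align(hemigrad:::mode_gradients(swapped, cfg), tpl)
  ai_a <- a$scores[1:p, ] - a$scores[p + 1:p, ]
  ai_b <- b$scores[1:p, ] - b$scores[p + 1:p, ]
  expect_equal(ai_b, -ai_a, tolerance = 1e-6)
})

test_that("embedding config validation catches bad parameters", {
  expect_error(embedding_config(row_density_kept = 0), "row_density_kept")
  expect_error(embedding_config(alpha = 1.5), "alpha")
  expect_error(embedding_config(n_components = 0), "n_components")
  expect_error(embedding_config(reference_mode = "XX"), "reference_mode|arg")
})
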