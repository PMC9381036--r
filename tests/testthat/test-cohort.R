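test_that("cohort spec validation rejects impossible designs", {
  expect_error(cohort_spec(h2_target = 1.2), "h2_target")
  expect_error(cohort_spec(noise_sd = 0), "noise_sd")
  expect_error(cohort_spec(n_mz_pairs = 0), "n_mz_pairs")
  expect_error(cohort_spec(n_singletons = -1), "n_singletons")
})

test_that("pedigree counts follow the family design", {
  spec <- cohort_spec(n_mz_pairs = 50, n_dz_pairs = 50, n_singletons = 20,
                      seed = 3)
  ped <- hemigrad:::make_pedigree(spec)
  expect_equal(nrow(ped), 220L)                    # 2*50 + 2*50 + 20
  expect_equal(length(unique(ped$family_id)), 120L)
  expect_equal(sum(ped$zygosity == "MZ"), 100L)
  expect_equal(sum(ped$zygosity == "DZ"), 100L)
  expect_equal(sum(ped$zygosity == "SINGLETON"), 20L)
  expect_false(anyDuplicated(ped$subject_id) > 0)
})

test_that("subject shifts respect zygosity under the variance partition", {
  # h2 = 1: all shift variance is genetic, so MZ co-twins are identical
  spec <- tiny_cohort_spec(seed = 8, n_mz_pairs = 30L, n_dz_pairs = 30L,
                           h2_target = 1)
  co <- make_timeseries_cohort(spec, generate_timeseries = FALSE)
  s <- co$ground_truth$subject_shift
  mz <- co$pedigree$zygosity == "MZ"
  mz_pairs <- matrix(s[mz], ncol = 2, byrow = TRUE)
  expect_equal(mz_pairs[, 1], mz_pairs[, 2])
  expect_equal(co$ground_truth$environmental[mz], rep(0, sum(mz)))
})

test_that("MZ shift correlation exceeds DZ correlation when h2 > 0", {
  cors <- vapply(1:50, function(i) {
    spec <- tiny_cohort_spec(seed = 100 + i, n_mz_pairs = 40L,
                             n_dz_pairs = 40L, h2_target = 0.6)
    co <- make_timeseries_cohort(spec, generate_timeseries = FALSE)
    s <- co$ground_truth$subject_shift
    zyg <- co$pedigree$zygosity
    mzp <- matrix(s[zyg == "MZ"], ncol = 2, byrow = TRUE)
    dzp <- matrix(s[zyg == "DZ"], ncol = 2, byrow = TRUE)
    c(cor(mzp[, 1], mzp[, 2]), cor(dzp[, 1], dzp[, 2]))
  }, numeric(2))
  expect_gt(mean(cors[1, ]), mean(cors[2, ]))
})

test_that("direct AE estimation on the injected shift recovers h2_target", {
  h2_hat <- vapply(1:20, function(i) {
    spec <- tiny_cohort_spec(seed = 200 + i, n_mz_pairs = 100L,
                             n_dz_pairs = 100L, n_singletons = 0L,
                             h2_target = 0.5)
    co <- make_timeseries_cohort(spec, generate_timeseries = FALSE)
    k <- kinship_from_pedigree(co$pedigree)
    fit_ae_ml(co$ground_truth$subject_shift, k)$h2
  }, 0)
  expect_lt(abs(mean(h2_hat) - 0.5), 0.05)
})

test_that("asym_scale = 0 gives identical left/right signal structure", {
  spec <- tiny_cohort_spec(seed = 5, asym_scale = 0, noise_sd = 1e-4)
  co <- make_timeseries_cohort(spec)
  s1 <- co$subjects[[1]][[1]]
  # with no asymmetry and negligible noise the hemispheres mix the same
  # basis identically
  expect_equal(s1$L, s1$R, tolerance = 1e-2)
  expect_equal(co$ground_truth$asym_field * spec$asym_scale, rep(0, 24))
})

test_that("cohort generation is deterministic and records its seed", {
  a <- make_timeseries_cohort(tiny_cohort_spec(seed = 6))
  b <- make_timeseries_cohort(tiny_cohort_spec(seed = 6))
  expect_identical(a$subjects[[3]][[1]]$L, b$subjects[[3]][[1]]$L)
  expect_equal(a$ground_truth$seed, 6L)
})

test_that("cohorts round-trip through the on-disk layout", {
  co <- make_timeseries_cohort(tiny_cohort_spec(
    seed = 9, n_mz_pairs = 2L, n_dz_pairs = 2L, n_singletons = 1L,
    n_parcels_per_hemisphere = 10L, n_timepoints = 30L))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  co2 <- read_cohort(dir)
  expect_equal(co2$pedigree$subject_id, co$pedigree$subject_id)
  expect_equal(co2$subjects[[1]][[1]]$L, co$subjects[[1]][[1]]$L,
               tolerance = 1e-11)
  expect_equal(co2$ground_truth$asym_field, co$ground_truth$asym_field,
               tolerance = 1e-12)
  expect_equal(co2$spec$h2_target, co$spec$h2_target)
})

test_that("malformed cohort directories raise named errors", {
  dir <- withr::local_tempdir()
  expect_error(read_cohort(file.path(dir, "absent")), "not found")
  expect_error(read_cohort(dir), "pedigree")
  co <- make_timeseries_cohort(tiny_cohort_spec(
    seed = 2, n_mz_pairs = 1L, n_dz_pairs = 1L, n_singletons = 0L,
    n_parcels_per_hemisphere = 8L, n_timepoints = 20L))
  write_cohort(co, dir)
  ped <- utils::read.csv(file.path(dir, "pedigree.csv"))
  utils::write.csv(ped[, setdiff(names(ped), "zygosity")],
                   file.path(dir, "pedigree.csv"), row.names = FALSE)
  expect_error(read_cohort(dir), "zygosity")
})

test_that("activation atlas honours designed loadings", {
  g <- make_parcel_geometry(30, seed = 3)
  designed <- matrix(pmax(cos(pi * g$latent), 0) + 0.6, 1)
  atl <- make_activation_atlas(4, g, designed_loadings = designed, seed = 2)
  expect_equal(atl$z[1, ], designed[1, ], ignore_attr = TRUE)
  # all-zero designed loading gives a flat map at the baseline
  atl0 <- make_activation_atlas(1, g, designed_loadings = matrix(0, 1, 30),
                                baseline = 0.2)
  expect_equal(atl0$z[1, ], rep(0.2, 30), ignore_attr = TRUE)
  # determinism contract for the random terms
  a1 <- make_activation_atlas(3, g, seed = 5)
  a2 <- make_activation_atlas(3, g, seed = 5)
  a3 <- make_activation_atlas(3, g, seed = 6)
  expect_identical(a1$z, a2$z)
  expect_false(isTRUE(all.equal(a1$z, a3$z)))
})
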