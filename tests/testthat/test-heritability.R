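make_test_ped <- function(n_mz, n_dz, n_sing = 0, seed = 1) {
  hemigrad:::make_pedigree(cohort_spec(
    n_mz_pairs = max(n_mz, 1), n_dz_pairs = max(n_dz, 1),
    n_singletons = n_sing, seed = seed))
}

# simulate a phenotype with additive-genetic fraction h2 on a pedigree
sim_phenotype <- function(ped, h2) {
  g <- numeric(nrow(ped))
  for (fam in unique(ped$family_id)) {
    idx <- which(ped$family_id == fam)
    zyg <- ped$zygosity[idx[1]]
    if (zyg == "MZ") g[idx] <- rnorm(1, 0, sqrt(h2))
    else if (zyg == "DZ") {
      shared <- rnorm(1, 0, sqrt(h2 / 2))
      g[idx] <- shared + rnorm(2, 0, sqrt(h2 / 2))
    } else g[idx] <- rnorm(length(idx), 0, sqrt(h2))
  }
  g + rnorm(nrow(ped), 0, sqrt(1 - h2))
}

test_that("kinship encodes the expected additive relatedness", {
  ped <- data.frame(
    subject_id = paste0("s", 1:7),
    family_id = c("f1", "f1", "f2", "f2", "f3", "f4", "f5"),
    zygosity = c("MZ", "MZ", "DZ", "DZ", "SINGLETON", "SINGLETON",
                 "SINGLETON"),
    age = 30, sex = 0)
  k <- kinship_from_pedigree(ped)
  expect_equal(diag(k), rep(1, 7), ignore_attr = TRUE)
  expect_equal(k[1, 2], 1)      # MZ co-twins
  expect_equal(k[3, 4], 0.5)    # DZ co-twins
  expect_equal(sum(k != 0), 7 + 4)
  expect_equal(k, t(k))
  expect_gte(min(eigen(k, symmetric = TRUE)$values), -1e-12)
  # all singletons give the identity
  sing <- ped[5:7, ]
  expect_equal(kinship_from_pedigree(sing), diag(3), ignore_attr = TRUE)
  # an MZ subject without a co-twin is an error
  expect_error(kinship_from_pedigree(ped[-1, ]), "exactly 2")
})

test_that("AE fit recovers heritability on twin phenotypes", {
  ped <- make_test_ped(200, 200, seed = 2)
  k <- kinship_from_pedigree(ped)
  eig <- eigen(k, symmetric = TRUE)
  set.seed(10)
  h2_hat <- replicate(10, fit_ae_ml(sim_phenotype(ped, 0.5), eig = eig)$h2)
  expect_lt(abs(mean(h2_hat) - 0.5), 0.1)
  # AE log-likelihood is never below the E-only fit
  f <- fit_ae_ml(sim_phenotype(ped, 0.5), eig = eig)
  expect_gte(f$loglik_ae, f$loglik_e - 1e-6)
  expect_gte(f$lrt, 0)
  expect_true(f$p_lrt > 0 && f$p_lrt <= 1)
  expect_true(f$h2 >= 0 && f$h2 <= 1)
  expect_equal(f$sigma2_g + f$sigma2_e, f$sigma2_p, tolerance = 1e-12)
})

test_that("h2 is invariant to affine rescaling of the phenotype", {
  ped <- make_test_ped(60, 60, seed = 3)
  eig <- eigen(kinship_from_pedigree(ped), symmetric = TRUE)
  set.seed(11)
  y <- sim_phenotype(ped, 0.4)
  f1 <- fit_ae_ml(y, eig = eig)
  f2 <- fit_ae_ml(-2.5 * y + 11, eig = eig)
  expect_equal(f1$h2, f2$h2, tolerance = 1e-5)
  expect_equal(f1$p_lrt, f2$p_lrt, tolerance = 1e-5)
})

test_that("a purely family-shared phenotype in MZ twins drives h2 to 1", {
  spec <- cohort_spec(n_mz_pairs = 80, n_dz_pairs = 1, n_singletons = 0,
                      seed = 4)
  ped <- hemigrad:::make_pedigree(spec)
  set.seed(12)
  fam_effect <- rnorm(length(unique(ped$family_id)))
  y <- fam_effect[as.integer(factor(ped$family_id))]
  f <- fit_ae_ml(y, kinship_from_pedigree(ped))
  expect_gt(f$h2, 0.98)
})

test_that("covariate effects are absorbed without biasing h2", {
  ped <- make_test_ped(150, 150, seed = 5)
  eig <- eigen(kinship_from_pedigree(ped), symmetric = TRUE)
  x <- heritability_covariates(ped)
  expect_equal(ncol(x), 5L)
  set.seed(13)
  h2_hat <- replicate(10, {
    y <- sim_phenotype(ped, 0.5) + 0.08 * (ped$age - mean(ped$age))
    fit_ae_ml(y, covariates = x, eig = eig)$h2
  })
  expect_lt(abs(mean(h2_hat) - 0.5), 0.12)
  # the age coefficient itself is recovered
  y <- sim_phenotype(ped, 0.5) + 0.08 * (ped$age - mean(ped$age))
  f <- fit_ae_ml(y, covariates = x, eig = eig)
  expect_lt(abs(coef(f)[["age"]] - 0.08), 0.05)
  # residual df accounting: n subjects minus intercept + 4 covariates
  expect_equal(f$df_resid, nrow(ped) - 5L)
})

test_that("degenerate designs and inputs are rejected", {
  ped <- make_test_ped(5, 5, seed = 6)
  k <- kinship_from_pedigree(ped)
  y <- rnorm(nrow(ped))
  expect_error(fit_ae_ml(y, k, covariates = cbind(1, 1:20, 2 * (1:20))),
               "singular")
  expect_error(fit_ae_ml(y[1:5], k), "match")
  expect_error(fit_ae_ml(y, k - 2 * diag(20)), "positive semidefinite")
})

test_that("heritability maps contrast heritable and noise parcels", {
  ped <- make_test_ped(120, 120, seed = 7)
  n <- nrow(ped)
  set.seed(14)
  heritable <- vapply(1:6, function(i) sim_phenotype(ped, 0.6), numeric(n))
  noise <- matrix(rnorm(n * 6), n)
  hm <- heritability_map(cbind(heritable, noise), ped)
  expect_equal(nrow(hm), 12L)
  expect_gt(mean(hm$h2[1:6]), mean(hm$h2[7:12]) + 0.2)
  expect_true(all(hm$p_fdr >= hm$p_lrt))
})
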