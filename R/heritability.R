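# Narrow-sense heritability by maximum-likelihood variance decomposition
# on twin pedigrees: y ~ N(X beta, sigma2_g * K + sigma2_e * I), with K the
# expected additive-relatedness matrix, profiled down to a 1-D search over
# h2 = sigma2_g / (sigma2_g + sigma2_e).

#' Expected additive-relatedness (kinship) matrix from a twin pedigree
#'
#' Diagonal 1; monozygotic co-twins 1; dizygotic co-twins 0.5; all other
#' pairs 0.  The matrix is block-diagonal by family and positive
#' semidefinite.
#'
#' @param pedigree data frame with columns `subject_id`, `family_id`,
#'   `zygosity` (MZ / DZ / SINGLETON); MZ and DZ subjects must appear in
#'   same-family pairs.
#' @return n x n numeric matrix with subject ids as dimnames, in pedigree
#'   row order.
#' @export
kinship_from_pedigree <- function(pedigree) {
  need <- c("subject_id", "family_id", "zygosity")
  miss <- setdiff(need, names(pedigree))
  if (length(miss))
    fail("pedigree is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(pedigree$subject_id))
    fail("duplicate subject ids in pedigree")
  n <- nrow(pedigree)
  k <- diag(n)
  for (fam in unique(pedigree$family_id)) {
    idx <- which(pedigree$family_id == fam)
    zyg <- unique(pedigree$zygosity[idx])
    if (length(zyg) != 1)
      fail("family ", fam, " mixes zygosity codes")
    if (zyg == "SINGLETON") next
    if (length(idx) != 2)
      fail(zyg, " family ", fam, " must contain exactly 2 subjects, has ",
           length(idx))
    k[idx[1], idx[2]] <- k[idx[2], idx[1]] <- if (zyg == "MZ") 1 else 0.5
  }
  dimnames(k) <- list(pedigree$subject_id, pedigree$subject_id)
  k
}

#' Standard covariate design for heritability models
#'
#' Intercept, centred age, sex, centred age squared and the centred
#' age-by-sex interaction.
#'
#' @param pedigree data frame with `age` and `sex` columns.
#' @return n x 5 design matrix.
#' @export
heritability_covariates <- function(pedigree) {
  age_c <- pedigree$age - mean(pedigree$age)
  cbind(intercept = 1, age = age_c, sex = pedigree$sex,
        age2 = age_c^2, age_sex = age_c * pedigree$sex)
}

# profile log-likelihood at fixed h2; eig is eigen(K), tz/ty the rotated
# design and phenotype.  beta and total variance are profiled out.
ae_profile_ll <- function(h2, lambda, tx, ty) {
  n <- length(ty)
  w <- h2 * lambda + (1 - h2)
  if (any(w <= 0)) return(list(ll = -Inf))
  sw <- sqrt(w)
  xw <- tx / sw
  yw <- ty / sw
  qrx <- qr(xw)
  if (qrx$rank < ncol(xw)) fail("singular covariate design")
  beta <- qr.coef(qrx, yw)
  rss <- sum(qr.resid(qrx, yw)^2)
  sigma2_p <- rss / n
  ll <- -0.5 * (n * log(2 * pi * sigma2_p) + n + sum(log(w)))
  list(ll = ll, beta = beta, sigma2_p = sigma2_p)
}

#' Maximum-likelihood AE variance decomposition
#'
#' Fits the additive-genetic-plus-unique-environment (AE) model
#' `y ~ N(X beta, sigma2_g K + sigma2_e I)` by full maximum likelihood.
#' One eigendecomposition of K rotates the model to independent
#' observations; beta and the total variance are profiled out analytically
#' and the likelihood is maximised by a bounded 1-D search over
#' `h2 = sigma2_g / sigma2_p` in [0, 1] (tolerance 1e-8, deterministic).
#' The AE fit is compared to the environment-only model (h2 = 0) with a
#' likelihood-ratio test; because h2 = 0 lies on the boundary of the
#' parameter space the null distribution is the 50:50 mixture of a point
#' mass at zero and chi-square(1), so `p_lrt = 0.5 * P(chi2_1 >= LRT)`
#' (and 1 when the LRT statistic is <= 0).
#'
#' @param phenotype numeric n-vector.
#' @param kinship n x n relatedness matrix from
#'   [kinship_from_pedigree()], or `NULL` when `eig` is supplied.
#' @param covariates n x c design matrix; default intercept only.
#' @param eig optional precomputed `eigen(kinship, symmetric = TRUE)`,
#'   reused across many phenotypes on the same pedigree.
#' @return an object of class `ae_fit` with fields `h2`, `sigma2_g`,
#'   `sigma2_e`, `sigma2_p`, `beta`, `loglik_ae`, `loglik_e`, `lrt`,
#'   `p_lrt`, `n`, `df_resid`.
#' @examples
#' ped <- data.frame(subject_id = paste0("s", 1:6),
#'                   family_id = c(1, 1, 2, 2, 3, 4),
#'                   zygosity = c("MZ", "MZ", "DZ", "DZ",
#'                                "SINGLETON", "SINGLETON"),
#'                   age = 30, sex = c(0, 0, 1, 1, 0, 1))
#' k <- kinship_from_pedigree(ped)
#' fit_ae_ml(rnorm(6), k)
#' @export
fit_ae_ml <- function(phenotype, kinship = NULL, covariates = NULL,
                      eig = NULL) {
  y <- as.numeric(phenotype)
  n <- length(y)
  if (anyNA(y)) fail("phenotype contains missing values")
  if (is.null(eig)) {
    if (is.null(kinship)) fail("supply kinship or its eigendecomposition")
    if (!isTRUE(all.equal(kinship, t(kinship), tolerance = 1e-9)))
      fail("kinship must be symmetric")
    eig <- eigen(kinship, symmetric = TRUE)
  }
  if (length(eig$values) != n)
    fail("kinship dimension (", length(eig$values),
         ") does not match phenotype length (", n, ")")
  if (min(eig$values) < -1e-8)
    fail("kinship is not positive semidefinite (min eigenvalue ",
         format(min(eig$values)), ")")
  lambda <- pmax(eig$values, 0)
  x <- if (is.null(covariates)) matrix(1, n, 1,
                                       dimnames = list(NULL, "intercept"))
       else as.matrix(covariates)
  if (n <= ncol(x) + 2)
    fail("need n > c + 2 observations (n = ", n, ", c = ", ncol(x), ")")
  tx <- crossprod(eig$vectors, x)
  ty <- as.vector(crossprod(eig$vectors, y))

  obj <- function(h2) ae_profile_ll(h2, lambda, tx, ty)$ll
  opt <- stats::optimize(obj, c(0, 1), maximum = TRUE, tol = 1e-8)
  # optimize() never lands exactly on the boundary; include the endpoints
  cand <- c(opt$maximum, 0, 1)
  lls <- c(opt$objective, obj(0), obj(1))
  h2 <- cand[which.max(lls)]
  best <- ae_profile_ll(h2, lambda, tx, ty)
  ll_e <- ae_profile_ll(0, lambda, tx, ty)$ll
  lrt <- 2 * (best$ll - ll_e)
  p_lrt <- if (lrt <= 0) 1 else 0.5 * stats::pchisq(lrt, df = 1,
                                                    lower.tail = FALSE)
  beta <- best$beta
  names(beta) <- colnames(x)
  structure(list(
    h2 = h2,
    sigma2_g = h2 * best$sigma2_p,
    sigma2_e = (1 - h2) * best$sigma2_p,
    sigma2_p = best$sigma2_p,
    beta = beta,
    loglik_ae = best$ll, loglik_e = ll_e,
    lrt = max(lrt, 0), p_lrt = p_lrt,
    n = n, df_resid = n - ncol(x)
  ), class = "ae_fit")
}

#' @export
print.ae_fit <- function(x, digits = 3, ...) {
  cat("AE maximum-likelihood variance decomposition (n =", x$n, ")\n")
  cat("  h2 =", format(x$h2, digits = digits),
      " (sigma2_g =", format(x$sigma2_g, digits = digits),
      ", sigma2_e =", format(x$sigma2_e, digits = digits), ")\n")
  cat("  LRT vs E-only =", format(x$lrt, digits = digits),
      " p =", format.pval(x$p_lrt, digits = digits), "\n")
  invisible(x)
}

#' @export
summary.ae_fit <- function(object, ...) {
  out <- c(h2 = object$h2, sigma2_g = object$sigma2_g,
           sigma2_e = object$sigma2_e, loglik_ae = object$loglik_ae,
           loglik_e = object$loglik_e, lrt = object$lrt,
           p_lrt = object$p_lrt, n = object$n)
  print(object, ...)
  cat("  covariate effects:\n")
  print(object$beta, ...)
  invisible(out)
}

#' @export
coef.ae_fit <- function(object, ...) object$beta

#' @export
logLik.ae_fit <- function(object, ...) {
  structure(object$loglik_ae, df = length(object$beta) + 2,
            nobs = object$n, class = "logLik")
}

#' Parcel-wise heritability map
#'
#' Fits [fit_ae_ml()] to every column of a phenotype stack (subjects x
#' parcels), reusing one eigendecomposition of the kinship matrix, and
#' applies BH-FDR over the likelihood-ratio p-values across parcels.
#'
#' @param ai_stack subjects x parcels matrix of phenotypes (rows aligned
#'   with the pedigree).
#' @param pedigree twin pedigree data frame.
#' @param covariates optional design matrix; default
#'   [heritability_covariates()] when age/sex are present, else intercept
#'   only.
#' @return data frame: parcel, h2, sigma2_g, sigma2_e, loglik_ae,
#'   loglik_e, p_lrt, p_fdr.
#' @export
heritability_map <- function(ai_stack, pedigree, covariates = NULL) {
  ai_stack <- as.matrix(ai_stack)
  if (nrow(ai_stack) != nrow(pedigree))
    fail("phenotype stack rows (", nrow(ai_stack),
         ") do not match pedigree (", nrow(pedigree), ")")
  if (is.null(covariates) && all(c("age", "sex") %in% names(pedigree)))
    covariates <- heritability_covariates(pedigree)
  k <- kinship_from_pedigree(pedigree)
  eig <- eigen(k, symmetric = TRUE)
  fits <- lapply(seq_len(ncol(ai_stack)), function(i)
    fit_ae_ml(ai_stack[, i], covariates = covariates, eig = eig))
  res <- data.frame(
    parcel = seq_len(ncol(ai_stack)),
    h2 = vapply(fits, `[[`, 0, "h2"),
    sigma2_g = vapply(fits, `[[`, 0, "sigma2_g"),
    sigma2_e = vapply(fits, `[[`, 0, "sigma2_e"),
    loglik_ae = vapply(fits, `[[`, 0, "loglik_ae"),
    loglik_e = vapply(fits, `[[`, 0, "loglik_e"),
    p_lrt = vapply(fits, `[[`, 0, "p_lrt")
  )
  res$p_fdr <- stats::p.adjust(res$p_lrt, method = "BH")
  res
}
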