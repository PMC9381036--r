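# Internal helpers shared across modules: seed derivation, scoped RNG,
# smooth fields on the sphere, and small validators.

#' Derive a child seed from a base seed and a label
#'
#' All randomness in the package flows from a single user-supplied seed.
#' Independent stages derive their own sub-seeds deterministically from the
#' base seed plus a stage label, so that adding or reordering stages never
#' perturbs the random stream of another stage.
#'
#' @param seed integer base seed.
#' @param ... labels (characters or integers) identifying the consumer.
#' @return an integer in [1, 2^31 - 2], usable with [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  parts <- paste(c(format(seed), vapply(list(...), format, "")), collapse = "/")
  codes <- utf8ToInt(parts)
  h <- 0
  for (ch in codes) h <- (h * 31 + ch) %% 2147483587
  as.integer(h + 1L)
}

# Evaluate expr with a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Pairwise great-circle angle (radians) between unit vectors in the rows of
# a and b.
angular_distance <- function(a, b = a) {
  cosang <- tcrossprod(a, b)
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  acos(cosang)
}

#' Smooth random field over sphere centroids
#'
#' Kernel-smooths i.i.d. Gaussian noise over a set of spherical centroids
#' with a Gaussian kernel in great-circle angle, then standardises to mean 0
#' and unit variance.  This is the package's model of a spatially
#' autocorrelated cortical map; the angular bandwidth (quoted as FWHM, the
#' neuroimaging convention for smoothing kernels) controls the smoothness
#' that spin-permutation nulls must respect.
#'
#' @param coords numeric matrix (parcels x 3) of unit centroids.
#' @param fwhm_deg kernel full width at half maximum in degrees of arc
#'   (default 30).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return numeric vector, one standardised value per parcel.
#' @export
smooth_sphere_field <- function(coords, fwhm_deg = 30, seed = NULL) {
  stopifnot(is.matrix(coords), ncol(coords) == 3)
  noise <- if (is.null(seed)) stats::rnorm(nrow(coords))
           else with_seed(seed, stats::rnorm(nrow(coords)))
  sigma <- fwhm_deg / (2 * sqrt(2 * log(2))) * pi / 180
  k <- exp(-angular_distance(coords)^2 / (2 * sigma^2))
  f <- as.vector(k %*% noise)
  as.vector(scale(f))
}

# stop() with a consistent prefix and no call noise
fail <- function(...) stop(..., call. = FALSE)

check_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    fail(name, " must be a numeric matrix")
  if (anyNA(x)) fail(name, " contains missing values")
  invisible(x)
}

frobenius <- function(x) sqrt(sum(x^2))
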