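# Synthetic meta-analytic activation atlas: term x parcel z-score maps with
# optional designed loadings so tests can plant a term on a chosen region.

#' Generate a synthetic term-by-parcel activation atlas
#'
#' Each undesigned term receives an independent smooth random field over the
#' parcel centroids (standardised, so values behave like activation
#' z-scores).  Rows of `designed_loadings` are used verbatim as that term's
#' map, letting a test construct, e.g., a "language-like" term concentrated
#' on parcels with a chosen sign of the asymmetry field; an all-zero
#' designed row yields a flat map equal to `baseline`.
#'
#' @param n_terms number of terms (>= 1).
#' @param geometry a [make_parcel_geometry()] result.
#' @param designed_loadings optional numeric matrix (terms x parcels) or a
#'   named list of per-parcel vectors for a subset of terms.
#' @param baseline scalar added to every map (default 0).
#' @param seed integer seed.
#' @return an object of class `activation_atlas`: list with `terms`
#'   (labels) and `z` (terms x parcels matrix).
#' @export
make_activation_atlas <- function(n_terms, geometry, designed_loadings = NULL,
                                  baseline = 0, seed = 1L) {
  if (n_terms < 1) fail("n_terms must be >= 1")
  p <- geometry$n_parcels
  terms <- sprintf("term%02d", seq_len(n_terms))
  z <- matrix(0, n_terms, p, dimnames = list(terms, NULL))
  designed <- rep(FALSE, n_terms)

  if (!is.null(designed_loadings)) {
    if (is.list(designed_loadings)) {
      idx <- match(names(designed_loadings), terms)
      if (anyNA(idx)) fail("designed_loadings names must match term labels")
      for (i in seq_along(idx)) {
        v <- as.numeric(designed_loadings[[i]])
        if (length(v) != p) fail("designed loading must have one value per parcel")
        z[idx[i], ] <- v
        designed[idx[i]] <- TRUE
      }
    } else {
      dl <- as.matrix(designed_loadings)
      if (ncol(dl) != p) fail("designed_loadings must have one column per parcel")
      k <- min(nrow(dl), n_terms)
      z[seq_len(k), ] <- dl[seq_len(k), ]
      designed[seq_len(k)] <- TRUE
    }
  }
  for (i in which(!designed))
    z[i, ] <- smooth_sphere_field(geometry$right, fwhm_deg = 30,
                                  seed = derive_seed(seed, "atlas-term", i))
  z <- z + baseline
  structure(list(terms = terms, z = z, seed = seed),
            class = "activation_atlas")
}

#' @export
print.activation_atlas <- function(x, ...) {
  cat("activation_atlas:", length(x$terms), "terms x", ncol(x$z),
      "parcels\n")
  invisible(x)
}
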