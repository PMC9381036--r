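# Hemispheric functional connectivity: the four Fisher-z correlation modes
# LL, RR (intra-hemispheric) and LR, RL (inter-hemispheric) per subject.

FISHER_CLAMP <- 1 - 1e-7

#' Hemispheric functional connectivity from parcellated time series
#'
#' Correlates all parcel pairs with the Pearson product-moment coefficient
#' and applies Fisher's z-transform (atanh), producing the four hemispheric
#' modes: LL and RR within a hemisphere, LR from left to right, and RL as
#' the transpose of LR.  |r| is clamped to 1 - 1e-7 before atanh so
#' degenerate perfectly correlated series stay finite, and the
#' self-correlation diagonal of LL/RR is set to 0 (the affinity stage
#' re-derives similarity, so the infinite atanh(1) diagonal carries no
#' information).
#'
#' @param ts_left,ts_right numeric matrices, parcels x timepoints, equal
#'   column counts and equal parcel counts.
#' @return an object of class `hemi_connectome` with matrices `ll`, `rr`,
#'   `lr`, `rl`.
#' @examples
#' ts <- matrix(rnorm(5 * 50), 5)
#' fc <- pearson_fisher_fc(ts, ts + rnorm(250, sd = 0.5))
#' max(abs(fc$rl - t(fc$lr)))  # 0 by construction
#' @export
pearson_fisher_fc <- function(ts_left, ts_right) {
  check_matrix(ts_left, "ts_left"); check_matrix(ts_right, "ts_right")
  if (ncol(ts_left) != ncol(ts_right))
    fail("timepoint counts differ between hemispheres (",
         ncol(ts_left), " vs ", ncol(ts_right), ")")
  if (nrow(ts_left) != nrow(ts_right))
    fail("parcel counts differ between hemispheres")
  if (ncol(ts_left) < 2) fail("need at least 2 timepoints")
  for (h in c("L", "R")) {
    m <- if (h == "L") ts_left else ts_right
    v <- apply(m, 1, stats::var)
    if (any(v == 0))
      fail("zero-variance series in hemisphere ", h, " at parcel(s): ",
           paste(which(v == 0), collapse = ", "))
  }
  fisher <- function(r) {
    r[r > FISHER_CLAMP] <- FISHER_CLAMP
    r[r < -FISHER_CLAMP] <- -FISHER_CLAMP
    atanh(r)
  }
  ll <- fisher(stats::cor(t(ts_left)))
  rr <- fisher(stats::cor(t(ts_right)))
  lr <- fisher(stats::cor(t(ts_left), t(ts_right)))
  diag(ll) <- 0
  diag(rr) <- 0
  structure(list(ll = ll, rr = rr, lr = lr, rl = t(lr),
                 n_parcels = nrow(ts_left)),
            class = "hemi_connectome")
}

#' @export
print.hemi_connectome <- function(x, ...) {
  cat("hemi_connectome:", x$n_parcels, "parcels per hemisphere",
      "(Fisher-z modes ll, rr, lr, rl)\n")
  invisible(x)
}

#' Average connectomes across sessions in Fisher-z space
#'
#' Element-wise mean of each mode over a list of equally shaped
#' connectomes.  Averaging happens in z space, after the transform.
#'
#' @param connectomes non-empty list of `hemi_connectome` objects.
#' @return a `hemi_connectome`.
#' @export
session_average <- function(connectomes) {
  if (!length(connectomes)) fail("session_average: empty connectome list")
  stopifnot(all(vapply(connectomes, inherits, TRUE, "hemi_connectome")))
  p <- connectomes[[1]]$n_parcels
  if (!all(vapply(connectomes, function(x) x$n_parcels, 0L) == p))
    fail("session_average: parcel counts differ across sessions")
  avg <- function(mode) Reduce(`+`, lapply(connectomes, `[[`, mode)) /
    length(connectomes)
  structure(list(ll = avg("ll"), rr = avg("rr"), lr = avg("lr"),
                 rl = avg("rl"), n_parcels = p),
            class = "hemi_connectome")
}

#' Session-averaged connectome for one cohort subject
#'
#' Convenience wrapper: runs [pearson_fisher_fc()] on every session of a
#' cohort subject and averages in z space.
#'
#' @param cohort a `hemigrad_cohort` with time series.
#' @param subject_id subject identifier.
#' @return a `hemi_connectome`.
#' @export
subject_connectome <- function(cohort, subject_id) {
  sess <- cohort$subjects[[subject_id]]
  if (is.null(sess)) fail("unknown subject: ", subject_id)
  session_average(lapply(sess, function(s) pearson_fisher_fc(s$L, s$R)))
}
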