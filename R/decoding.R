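# Meta-analytic lateralization decoding: relate a normalized asymmetry map
# to term-wise activation maps via a bin-weighted score.  Positive scores
# mean leftward-lateralized terms.

#' Split a signed asymmetry map into hemispheric projections
#'
#' Leftward (positive) values go on the left map, the magnitudes of
#' rightward (negative) values on the right map; all other entries become
#' zero.  `left - right` reconstructs the input exactly.
#'
#' @param d_map signed numeric p-vector (positive = leftward).
#' @return list with numeric vectors `left` and `right`.
#' @export
hemispheric_projection <- function(d_map) {
  d <- as.numeric(d_map)
  list(left = pmax(d, 0), right = pmax(-d, 0))
}

#' Equal-count bins along an asymmetry map
#'
#' Partitions parcels into `n_bins` rank bins of (near-)equal size along
#' the map; ties are broken by parcel index.  Bin 1 holds the most
#' rightward (most negative) parcels and bin `n_bins` the most leftward.
#'
#' @param d_map numeric p-vector.
#' @param n_bins number of bins (default 20, i.e. 5\% of parcels per bin);
#'   must not exceed p.
#' @return integer vector of bin assignments in 1..n_bins.
#' @export
quantile_bins <- function(d_map, n_bins = 20L) {
  p <- length(d_map)
  if (p < n_bins)
    fail("cannot form ", n_bins, " bins from ", p, " parcels")
  r <- rank(d_map, ties.method = "first")
  as.integer(ceiling(r * n_bins / p))
}

#' Bin-weighted lateralization score of an activation term
#'
#' For each of the `n_bins` equal-count bins of the asymmetry map, the
#' term's suprathreshold activation (z > `z_threshold`) is averaged (0 when
#' no parcel in the bin passes the mask), and the score is the sum over
#' bins of that mean activation times the bin's mean asymmetry.  A
#' parcel-level variant, `sum(1[z_i > thr] * z_i * d_i)`, is co-reported
#' for sensitivity since the binned and parcel-wise formulations are both
#' defensible readings of the weighted-score construction.
#'
#' @param term_z numeric p-vector of activation z-scores for one term.
#' @param d_map numeric p-vector of normalized asymmetry (positive =
#'   leftward), indexed like `term_z`.
#' @param n_bins number of asymmetry bins (default 20).
#' @param z_threshold activation mask threshold (default 0.5).
#' @return list with `score` (binned, signed; positive = leftward),
#'   `parcel_score`, and `bin_profile` (data frame: bin, mean masked z,
#'   mean asymmetry, parcels passing the mask).
#' @examples
#' lateralization_score(c(0.6, 0.4, 1.0), c(0.5, -0.2, -0.8), n_bins = 3)
#' @export
lateralization_score <- function(term_z, d_map, n_bins = 20L,
                                 z_threshold = 0.5) {
  term_z <- as.numeric(term_z)
  d <- as.numeric(d_map)
  if (length(term_z) != length(d))
    fail("term map and asymmetry map differ in length")
  bins <- quantile_bins(d, n_bins)
  prof <- data.frame(bin = seq_len(n_bins), mean_z = 0,
                     mean_asym = NA_real_, n_masked = 0L)
  for (b in seq_len(n_bins)) {
    in_b <- bins == b
    prof$mean_asym[b] <- mean(d[in_b])
    masked <- in_b & term_z > z_threshold
    prof$n_masked[b] <- sum(masked)
    if (any(masked)) prof$mean_z[b] <- mean(term_z[masked])
  }
  list(score = sum(prof$mean_z * prof$mean_asym),
       parcel_score = sum((term_z > z_threshold) * term_z * d),
       bin_profile = prof)
}

#' Decode all terms of an activation atlas against an asymmetry map
#'
#' @param atlas an `activation_atlas` (or terms x parcels matrix with row
#'   names).
#' @param d_map normalized asymmetry p-vector.
#' @param n_bins,z_threshold passed to [lateralization_score()].
#' @return data frame (class `decoding_table`): term, weighted_score,
#'   parcel_score; one row per term.
#' @export
decode_terms <- function(atlas, d_map, n_bins = 20L, z_threshold = 0.5) {
  z <- if (inherits(atlas, "activation_atlas")) atlas$z else as.matrix(atlas)
  if (is.null(rownames(z))) rownames(z) <- sprintf("term%02d", seq_len(nrow(z)))
  scores <- lapply(seq_len(nrow(z)), function(i)
    lateralization_score(z[i, ], d_map, n_bins, z_threshold))
  res <- data.frame(term = rownames(z),
                    weighted_score = vapply(scores, `[[`, 0, "score"),
                    parcel_score = vapply(scores, `[[`, 0, "parcel_score"),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("decoding_table", class(res))
  res
}

#' Order terms along the lateralization dominance axis
#'
#' Descending binned weighted score (most leftward first); ties broken by
#' term label.
#'
#' @param table a [decode_terms()] result.
#' @return character vector of term labels.
#' @export
rank_terms <- function(table) {
  if (!nrow(table)) fail("empty decoding table")
  table$term[order(-table$weighted_score, table$term)]
}
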