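# Cross-species / cross-parcellation transfer of effect maps through a
# supplied row-stochastic mapping, and similarity with spin significance.
# The mapping itself (a joint-embedding alignment) is an input artifact;
# learning it is out of scope here.

#' Row-stochastic species mapping
#'
#' Validates and wraps a nonnegative weight matrix whose rows (target
#' parcels) sum to 1.
#'
#' @param weights q_target x p_source numeric matrix.
#' @param direction free-text label (e.g. "human_to_macaque").
#' @param variant `"via_left"`, `"via_right"` or other label recording
#'   which hemisphere's alignment produced the mapping.
#' @return an object of class `species_mapping`.
#' @export
species_mapping <- function(weights, direction = "A_to_B",
                            variant = "via_right") {
  check_matrix(weights, "weights")
  if (min(weights) < 0) fail("mapping weights must be nonnegative")
  rs <- rowSums(weights)
  if (any(rs == 0)) fail("mapping has all-zero row(s)")
  if (max(abs(rs - 1)) > 1e-9)
    fail("mapping rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  structure(list(weights = weights, direction = direction,
                 variant = variant),
            class = "species_mapping")
}

#' @export
print.species_mapping <- function(x, ...) {
  cat("species_mapping:", nrow(x$weights), "target x", ncol(x$weights),
      "source parcels (", x$direction, ",", x$variant, ")\n")
  invisible(x)
}

#' Carry a parcel map through a species mapping
#'
#' Each target parcel receives the weighted average of the source map
#' under the mapping's row weights.  Typically applied to a Cohen's d map,
#' whose normalisation makes effect sizes comparable across samples.
#'
#' @param source_map numeric p-vector on the source parcellation.
#' @param mapping a [species_mapping()] with p source columns.
#' @return numeric q-vector on the target parcellation.
#' @export
apply_species_mapping <- function(source_map, mapping) {
  stopifnot(inherits(mapping, "species_mapping"))
  if (length(source_map) != ncol(mapping$weights))
    fail("source map length (", length(source_map),
         ") does not match mapping source dimension (",
         ncol(mapping$weights), ")")
  as.vector(mapping$weights %*% as.numeric(source_map))
}

#' Average the left- and right-alignment transfers
#'
#' Cross-species alignments can be computed through either hemisphere;
#' averaging the two element-wise reduces the systematic bias of a single
#' alignment path.
#'
#' @param map_via_left,map_via_right numeric q-vectors of equal length.
#' @return their element-wise mean.
#' @export
average_bidirectional <- function(map_via_left, map_via_right) {
  if (length(map_via_left) != length(map_via_right))
    fail("maps differ in length")
  (map_via_left + map_via_right) / 2
}

#' Cross-species similarity with spin significance
#'
#' Pearson and Spearman correlations between a transferred map and a
#' native map on the same target parcellation, each with a
#' spin-permutation p-value on the target sphere geometry.
#'
#' @param mapped_map,native_map numeric q-vectors on the target
#'   parcellation.
#' @param coords q x 3 unit centroids of the target parcellation.
#' @param n_perm,seed passed to [spin_corr_test()].
#' @return list with `pearson` and `spearman` [spin_corr_test()] results.
#' @export
cross_species_similarity <- function(mapped_map, native_map, coords,
                                     n_perm = 1000L, seed = 1L) {
  list(
    pearson = spin_corr_test(mapped_map, native_map, coords,
                             method = "pearson", n_perm = n_perm,
                             seed = derive_seed(seed, "xsp-pearson")),
    spearman = spin_corr_test(mapped_map, native_map, coords,
                              method = "spearman", n_perm = n_perm,
                              seed = derive_seed(seed, "xsp-spearman"))
  )
}
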