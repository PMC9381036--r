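# Asymmetry indices and group-level statistics.  Positive AI = leftward
# dominance (left minus right); any figure-style sign flip is metadata
# only, the stored numerics always use the raw L - R convention.

#' Raw asymmetry index: left minus right
#'
#' Element-wise left minus right gradient scores at homologous parcels.
#' For the intra-hemispheric pattern the inputs are the aligned LL and RR
#' scores; for the inter-hemispheric pattern, LR and RL.
#'
#' @param left_scores,right_scores numeric matrices (or vectors) of equal
#'   shape, rows = homologous parcels.
#' @return matrix (or vector) of the same shape; positive values are
#'   leftward.
#' @export
asymmetry_index <- function(left_scores, right_scores) {
  if (!all(dim(as.matrix(left_scores)) == dim(as.matrix(right_scores))))
    fail("left and right score shapes differ")
  left_scores - right_scores
}

#' Normalized asymmetry index: (L - R) / (L + R) after a positivity shift
#'
#' Gradient scores are signed, so the ratio form requires rescaling the
#' score distribution to positive values first.  Both hemispheres are
#' shifted by one common constant `c = -min(all scores) + eps`, with
#' `eps` a fixed fraction of the score range (default 1\%), and the index
#' is `(L' - R') / (L' + R')`.  When normalising a whole cohort, compute
#' the shift once from the pooled scores via [ai_shift_constant()] and pass
#' it in, so every subject shares the same rescaling.
#'
#' @param left_scores,right_scores numeric matrices of equal shape.
#' @param shift positivity shift constant; default derives it from the two
#'   inputs alone.
#' @param eps_frac fraction of the pooled score range added beyond the
#'   minimum (default 0.01).
#' @return matrix of normalized AI values.
#' @export
normalized_asymmetry_index <- function(left_scores, right_scores,
                                       shift = NULL, eps_frac = 0.01) {
  if (!all(dim(as.matrix(left_scores)) == dim(as.matrix(right_scores))))
    fail("left and right score shapes differ")
  if (is.null(shift))
    shift <- ai_shift_constant(left_scores, right_scores,
                               eps_frac = eps_frac)
  l <- left_scores + shift
  r <- right_scores + shift
  denom <- l + r
  if (any(denom <= 0))
    fail("shift policy violated: L' + R' <= 0 at ", sum(denom <= 0),
         " entr(ies); increase the shift")
  (l - r) / denom
}

#' Common positivity shift for normalized AI
#'
#' @param ... numeric score arrays pooled across hemispheres (and, for a
#'   cohort, across subjects).
#' @param eps_frac fraction of the pooled range added beyond the minimum.
#' @return scalar shift constant.
#' @export
ai_shift_constant <- function(..., eps_frac = 0.01) {
  pooled <- unlist(lapply(list(...), as.numeric))
  -min(pooled) + eps_frac * diff(range(pooled))
}

#' Group-level one-sample statistics of an asymmetry map
#'
#' Per parcel: one-sample t test of the subject AIs against zero (two
#' sided), Benjamini-Hochberg FDR across the supplied scope (by default all
#' parcels of the map), and Cohen's d = mean / SD (sample SD).  The
#' identity t = d * sqrt(n) holds exactly.  Parcels with zero variance get
#' NA statistics with a warning.
#'
#' @param ai_stack numeric matrix, subjects x parcels (>= 3 subjects).
#' @param labels optional parcel labels for the output table.
#' @return an object of class `asym_stats`: data frame with columns
#'   `parcel`, `mean_ai`, `t`, `df`, `p`, `p_fdr`, `cohens_d`; the subject
#'   count is attached as attribute `n`.
#' @examples
#' ai <- matrix(rnorm(30 * 8, mean = 0.2), 30)
#' group_asymmetry_stats(ai)
#' @export
group_asymmetry_stats <- function(ai_stack, labels = NULL) {
  ai_stack <- as.matrix(ai_stack)
  n <- nrow(ai_stack)
  if (n < 3) fail("need at least 3 subjects for group statistics")
  if (anyNA(ai_stack)) fail("ai_stack contains missing values")
  m <- colMeans(ai_stack)
  s <- apply(ai_stack, 2, stats::sd)
  zero_var <- s == 0
  if (any(zero_var)) {
    warning("zero-variance AI at parcel(s) ",
            paste(which(zero_var), collapse = ", "),
            "; statistics set to NA")
    s[zero_var] <- NA_real_
  }
  d <- m / s
  t_stat <- d * sqrt(n)
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  res <- data.frame(
    parcel = if (is.null(labels)) seq_along(m) else labels,
    mean_ai = m, t = t_stat, df = n - 1L, p = p,
    p_fdr = stats::p.adjust(p, method = "BH"),
    cohens_d = d,
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  attr(res, "n") <- n
  # figure convention only: some displays flip the sign so that rightward
  # dominance plots upward; stored numerics always use raw L - R
  attr(res, "display_sign") <- 1
  class(res) <- c("asym_stats", class(res))
  res
}

#' @export
print.asym_stats <- function(x, ...) {
  n <- attr(x, "n")
  sig <- sum(x$p_fdr < 0.05, na.rm = TRUE)
  cat("Group asymmetry statistics: n =", n, "subjects,", nrow(x),
      "units;", sig, "significant at P_FDR < 0.05\n")
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 3)
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more rows)\n", sep = "")
  invisible(x)
}

#' Network-level asymmetry summary
#'
#' Averages each subject's AI over the parcels of every network, then runs
#' the same one-sample machinery across subjects, with BH-FDR across
#' networks.  Networks can then be ranked from leftward (largest positive
#' t) to rightward (most negative t) dominance.
#'
#' @param ai_stack subjects x parcels AI matrix.
#' @param network_labels factor/character of length parcels; every parcel
#'   must be labelled.
#' @return an `asym_stats` data frame with one row per network, ordered by
#'   descending t.
#' @export
network_summary <- function(ai_stack, network_labels) {
  ai_stack <- as.matrix(ai_stack)
  if (length(network_labels) != ncol(ai_stack))
    fail("network_labels must label every parcel (got ",
         length(network_labels), " labels for ", ncol(ai_stack), " parcels)")
  if (anyNA(network_labels)) fail("unlabeled parcel(s) present")
  labs <- as.character(network_labels)
  nets <- unique(labs)
  net_means <- vapply(nets, function(nw)
    rowMeans(ai_stack[, labs == nw, drop = FALSE]), numeric(nrow(ai_stack)))
  res <- group_asymmetry_stats(net_means, labels = nets)
  res[order(res$t, decreasing = TRUE), , drop = FALSE]
}
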