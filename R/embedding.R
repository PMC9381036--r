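# Diffusion-map gradients: row sparsification, normalized-angle affinity,
# anisotropic diffusion embedding, group template with an explicit sign
# convention, and Procrustes alignment of individuals to the template.

#' Embedding configuration
#'
#' @param row_density_kept fraction of entries kept per connectivity row
#'   (default 0.10, i.e. the matrix is thresholded at the 90th percentile
#'   row-wise).
#' @param alpha anisotropic-diffusion exponent in [0, 1]; 0.5 balances
#'   geometry against sampling density (default 0.5).
#' @param n_components number of gradients extracted (default 10).
#' @param diffusion_time nonnegative diffusion time t; 0 selects the
#'   automatic lambda/(1 - lambda) scaling (default 0).
#' @param kernel affinity kernel; only `"normalized_angle"` is implemented.
#' @param reference_mode which intra-hemispheric mode supplies the group
#'   template, `"LL"` (default) or `"RR"`.
#' @return an object of class `embedding_config`.
#' @export
embedding_config <- function(row_density_kept = 0.10, alpha = 0.5,
                             n_components = 10L, diffusion_time = 0,
                             kernel = "normalized_angle",
                             reference_mode = c("LL", "RR")) {
  if (row_density_kept <= 0 || row_density_kept > 1)
    fail("row_density_kept must lie in (0, 1]")
  if (alpha < 0 || alpha > 1) fail("alpha must lie in [0, 1]")
  if (n_components < 1) fail("n_components must be >= 1")
  if (diffusion_time < 0) fail("diffusion_time must be >= 0")
  kernel <- match.arg(kernel)
  structure(list(row_density_kept = row_density_kept, alpha = alpha,
                 n_components = as.integer(n_components),
                 diffusion_time = diffusion_time, kernel = kernel,
                 reference_mode = match.arg(reference_mode)),
            class = "embedding_config")
}

#' Row-wise sparsification of a connectivity matrix
#'
#' Keeps, in every row, the `ceiling(density_kept * p)` largest entries by
#' signed value and zeroes the rest.  Ties at the threshold are broken
#' deterministically in favour of the lower column index.
#'
#' @param mat square numeric matrix.
#' @param density_kept fraction of entries kept per row, in (0, 1].
#' @return matrix of the same shape with the weak entries zeroed.
#' @export
sparsify_rows <- function(mat, density_kept = 0.10) {
  check_matrix(mat, "mat")
  if (nrow(mat) != ncol(mat)) fail("sparsify_rows expects a square matrix")
  if (density_kept <= 0 || density_kept > 1)
    fail("density_kept must lie in (0, 1]")
  p <- ncol(mat)
  keep <- ceiling(density_kept * p)
  if (keep >= p) return(mat)
  out <- matrix(0, p, p)
  for (i in seq_len(p)) {
    # order() with the radix method is stable: among tied values the lower
    # column index wins
    idx <- order(mat[i, ], decreasing = TRUE, method = "radix")[seq_len(keep)]
    out[i, idx] <- mat[i, idx]
  }
  out
}

#' Normalized-angle affinity between connectivity rows
#'
#' `affinity(i, j) = 1 - arccos(cosine(row_i, row_j)) / pi`: 1 for
#' identical directions, 0.5 for orthogonal rows, 0 for antiparallel rows.
#' Symmetric with unit diagonal; values in [0, 1].
#'
#' @param mat numeric matrix whose rows are connectivity profiles (e.g. the
#'   output of [sparsify_rows()]).
#' @return symmetric p x p affinity matrix.
#' @export
normalized_angle_affinity <- function(mat) {
  check_matrix(mat, "mat")
  norms <- sqrt(rowSums(mat^2))
  if (any(norms == 0))
    fail("all-zero row(s) at parcel(s): ",
         paste(which(norms == 0), collapse = ", "),
         "; cannot form an affinity")
  u <- mat / norms
  cosang <- tcrossprod(u)
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  aff <- 1 - acos(cosang) / pi
  diag(aff) <- 1
  aff
}

# connectivity check on the nonzero pattern (single BFS)
graph_connected <- function(w) {
  p <- nrow(w)
  adj <- w > 0
  seen <- logical(p)
  frontier <- 1L
  seen[1L] <- TRUE
  while (length(frontier)) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' Diffusion-map embedding of an affinity matrix
#'
#' Applies the anisotropic normalisation `W' = D^-alpha W D^-alpha`, forms
#' the Markov operator `M = row-normalised W'`, and eigendecomposes it
#' through the equivalent symmetric operator.  The trivial constant
#' eigenvector (eigenvalue 1) is dropped; component c is scaled by
#' `lambda_c^t` when `diffusion_time > 0`, otherwise by
#' `lambda_c / (1 - lambda_c)`.  The variance-explained fraction of a
#' retained component is its eigenvalue over the sum of all positive
#' nontrivial eigenvalues, so the fractions sum to at most 1.
#'
#' @param affinity symmetric nonnegative matrix with a connected nonzero
#'   pattern.
#' @param config an [embedding_config()] (or arguments for one).
#' @return an object of class `gradient_set`: `scores` (p x k, columns
#'   G1...Gk ordered by descending eigenvalue), `eigenvalues` and
#'   `variance_explained`.
#' @export
diffusion_embedding <- function(affinity, config = embedding_config()) {
  if (!inherits(config, "embedding_config"))
    config <- do.call(embedding_config, config)
  check_matrix(affinity, "affinity")
  p <- nrow(affinity)
  if (p != ncol(affinity)) fail("affinity must be square")
  if (max(abs(affinity - t(affinity))) > 1e-8)
    fail("affinity must be symmetric")
  if (min(affinity) < 0) fail("affinity must be nonnegative")
  if (!graph_connected(affinity))
    fail("affinity graph is disconnected; lower the sparsity ",
         "(increase row_density_kept)")

  alpha <- config$alpha
  d <- rowSums(affinity)
  w1 <- affinity / outer(d^alpha, d^alpha)
  d1 <- rowSums(w1)
  # M = D1^-1 W' is similar to the symmetric S = D1^-1/2 W' D1^-1/2
  s <- w1 / outer(sqrt(d1), sqrt(d1))
  s <- (s + t(s)) / 2
  eig <- eigen(s, symmetric = TRUE)
  lambdas <- eig$values
  psi <- eig$vectors / sqrt(d1)  # eigenvectors of M, rows scaled

  # normalise against the trivial component so scores are comparable across
  # subjects, then drop it
  psi <- psi / psi[1, 1]
  lambdas_nt <- lambdas[-1]
  psi <- psi[, -1, drop = FALSE]

  k <- config$n_components
  if (length(lambdas_nt) < k) {
    warning("only ", length(lambdas_nt), " nontrivial components available; ",
            "truncating from ", k)
    k <- length(lambdas_nt)
  }
  lam_k <- lambdas_nt[seq_len(k)]
  scale_k <- if (config$diffusion_time > 0) lam_k^config$diffusion_time
             else lam_k / (1 - lam_k)
  scores <- sweep(psi[, seq_len(k), drop = FALSE], 2, scale_k, `*`)
  colnames(scores) <- paste0("G", seq_len(k))

  denom <- sum(lambdas_nt[lambdas_nt > 0])
  structure(list(scores = scores, eigenvalues = lam_k,
                 variance_explained = lam_k / denom,
                 config = config),
            class = "gradient_set")
}

#' @export
print.gradient_set <- function(x, ...) {
  k <- min(3L, ncol(x$scores))
  cat("gradient_set:", nrow(x$scores), "parcels x", ncol(x$scores),
      "components; variance explained",
      paste0(sprintf("%.1f%%", 100 * x$variance_explained[seq_len(k)]),
             collapse = ", "),
      if (ncol(x$scores) > k) "..." else "", "\n")
  if (!is.null(x$procrustes_residual))
    cat("  aligned (Procrustes residual ",
        sprintf("%.3g", x$procrustes_residual), ")\n", sep = "")
  invisible(x)
}

# sparsify -> affinity -> embed, the per-mode gradient pipeline
mode_gradients <- function(mat, config) {
  diffusion_embedding(
    normalized_angle_affinity(sparsify_rows(mat, config$row_density_kept)),
    config)
}

#' Build the group gradient template
#'
#' Embeds the group-mean reference connectome and fixes the sign of every
#' component against an orientation anchor: each column is flipped so its
#' correlation with the anchor map is nonnegative (columns uncorrelated
#' with the anchor fall back to making their largest-magnitude entry
#' positive).  The template is used only to match the order and direction
#' of individual gradients; individuals are never rescaled by it.
#'
#' @param mean_reference_connectome p x p group-mean connectivity matrix of
#'   the reference mode.
#' @param config an [embedding_config()].
#' @param anchor optional per-parcel orientation anchor map; the default is
#'   the row degree of the sparsified matrix, a crude proxy for the
#'   principal functional axis.  Supplying a known reference map (an atlas
#'   axis, a prior-study gradient) makes the sign convention explicit and
#'   portable across datasets.
#' @return an object of class `gradient_template` (a `gradient_set` plus
#'   the anchor and the applied signs).
#' @export
build_template <- function(mean_reference_connectome,
                           config = embedding_config(), anchor = NULL) {
  if (!inherits(config, "embedding_config"))
    config <- do.call(embedding_config, config)
  sp <- sparsify_rows(mean_reference_connectome, config$row_density_kept)
  gs <- diffusion_embedding(normalized_angle_affinity(sp), config)
  if (is.null(anchor)) anchor <- rowSums(sp)
  if (length(anchor) != nrow(gs$scores))
    fail("anchor must have one value per parcel")
  signs <- vapply(seq_len(ncol(gs$scores)), function(c) {
    r <- suppressWarnings(stats::cor(gs$scores[, c], anchor))
    if (is.na(r) || abs(r) < 1e-12) {
      i <- which.max(abs(gs$scores[, c]))
      if (gs$scores[i, c] < 0) -1 else 1
    } else if (r < 0) -1 else 1
  }, 0)
  gs$scores <- sweep(gs$scores, 2, signs, `*`)
  gs$anchor <- anchor
  gs$component_signs <- signs
  class(gs) <- c("gradient_template", class(gs))
  gs
}

#' Procrustes alignment of a gradient set to a template
#'
#' Finds the orthogonal matrix R (reflections permitted) minimising
#' `||source %*% R - template||_F` and returns the rotated scores.  No
#' scaling and no translation are applied, so the template matters only
#' for matching the order and direction of components; the post-rotation
#' Frobenius residual is recorded as the alignment quality.
#'
#' @param source a `gradient_set` (or p x k score matrix).
#' @param template a `gradient_template` (or p x k score matrix) of the
#'   same shape.
#' @return the aligned `gradient_set`, with `rotation` and
#'   `procrustes_residual` fields added.
#' @export
procrustes_align <- function(source, template) {
  src <- if (inherits(source, "gradient_set")) source
         else structure(list(scores = as.matrix(source)),
                        class = "gradient_set")
  tpl <- if (inherits(template, "gradient_set")) template$scores
         else as.matrix(template)
  x <- src$scores
  if (!all(dim(x) == dim(tpl)))
    fail("source and template shapes differ (",
         paste(dim(x), collapse = "x"), " vs ",
         paste(dim(tpl), collapse = "x"), ")")
  sv <- svd(crossprod(x, tpl))
  r <- sv$u %*% t(sv$v)
  src$scores <- x %*% r
  colnames(src$scores) <- colnames(tpl)
  src$rotation <- r
  src$procrustes_residual <- frobenius(src$scores - tpl)
  src
}

#' Aligned gradients for all four hemispheric modes
#'
#' Independently sparsifies, affinitises, embeds and Procrustes-aligns each
#' of the LL, RR, LR, RL connectivity modes of one subject to the single
#' group template.
#'
#' @param connectome a `hemi_connectome`.
#' @param template the group `gradient_template`.
#' @param config the [embedding_config()] the template was built with.
#' @return named list of four aligned `gradient_set`s (`LL`, `RR`, `LR`,
#'   `RL`).
#' @export
embed_all_modes <- function(connectome, template,
                            config = embedding_config()) {
  stopifnot(inherits(connectome, "hemi_connectome"))
  if (!inherits(config, "embedding_config"))
    config <- do.call(embedding_config, config)
  modes <- list(LL = connectome$ll, RR = connectome$rr,
                LR = connectome$lr, RL = connectome$rl)
  lapply(modes, function(m)
    procrustes_align(mode_gradients(m, config), template))
}

#' Joint two-hemisphere embedding
#'
#' Assembles the full 2p x 2p matrix `[[LL, LR], [RL, RR]]` (left-hemisphere
#' parcels first), embeds it as a single system, and optionally aligns to a
#' joint template.  The asymmetry index of the joint variant is the
#' difference between homologous rows (row i minus row p + i).
#'
#' @param connectome a `hemi_connectome`.
#' @param config an [embedding_config()].
#' @param template optional joint `gradient_template` (2p rows) to align to.
#' @return a `gradient_set` with 2p rows.
#' @export
embed_joint <- function(connectome, config = embedding_config(),
                        template = NULL) {
  stopifnot(inherits(connectome, "hemi_connectome"))
  if (!inherits(config, "embedding_config"))
    config <- do.call(embedding_config, config)
  full <- rbind(cbind(connectome$ll, connectome$lr),
                cbind(connectome$rl, connectome$rr))
  gs <- mode_gradients(full, config)
  if (!is.null(template)) gs <- procrustes_align(gs, template)
  gs
}

#' Group-mean connectome of one mode
#'
#' Element-wise mean over subjects of one connectivity mode, used as the
#' input of [build_template()].  `"joint"` assembles the full 2p x 2p
#' two-hemisphere matrix (left parcels first) before averaging.
#'
#' @param connectomes list of `hemi_connectome` objects.
#' @param mode `"LL"`, `"RR"` or `"joint"`.
#' @return a p x p (or 2p x 2p) matrix.
#' @export
group_mean_mode <- function(connectomes, mode = c("LL", "RR", "joint")) {
  mode <- match.arg(mode)
  pick <- switch(mode,
    LL = function(x) x$ll,
    RR = function(x) x$rr,
    joint = function(x) rbind(cbind(x$ll, x$lr), cbind(x$rl, x$rr)))
  Reduce(`+`, lapply(connectomes, pick)) / length(connectomes)
}
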