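# Shared fixtures and independent oracles for the test suite.  Fixtures are
# generated in code at test time; nothing is read from disk.

# a deliberately small cohort for fast module tests
tiny_cohort_spec <- function(seed = 1L, ...) {
  args <- list(n_mz_pairs = 5L, n_dz_pairs = 5L, n_singletons = 2L,
               n_parcels_per_hemisphere = 24L, n_timepoints = 80L,
               n_sessions = 1L, seed = seed)
  do.call(cohort_spec, utils::modifyList(args, list(...)))
}

# brute-force Pearson correlation + Fisher z, written from the defining
# formulas (independent of stats::cor)
oracle_pearson_z <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  r <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  r <- max(min(r, 1 - 1e-7), -(1 - 1e-7))
  atanh(r)
}

# brute-force per-row top-k selection by signed value, ties to lower index
oracle_sparsify <- function(mat, keep) {
  out <- matrix(0, nrow(mat), ncol(mat))
  for (i in seq_len(nrow(mat))) {
    v <- mat[i, ]
    sel <- integer(0)
    for (k in seq_len(keep)) {
      cand <- setdiff(which(v == max(v[setdiff(seq_along(v), sel)])), sel)
      sel <- c(sel, min(cand))
      v[min(cand)] <- -Inf
    }
    out[i, sel] <- mat[i, sel]
  }
  out
}

# dense diffusion-map oracle: builds the Markov operator explicitly and
# eigendecomposes it as a nonsymmetric matrix (different route from the
# package's symmetric-equivalence implementation)
oracle_diffusion <- function(w, alpha = 0.5, k = 10) {
  d <- rowSums(w)
  w1 <- w / outer(d^alpha, d^alpha)
  m <- w1 / rowSums(w1)
  e <- eigen(m)
  ord <- order(Re(e$values), decreasing = TRUE)
  lam <- Re(e$values)[ord][-1]
  vec <- Re(e$vectors)[, ord, drop = FALSE][, -1, drop = FALSE]
  sweep(vec[, seq_len(k), drop = FALSE], 2,
        lam[seq_len(k)] / (1 - lam[seq_len(k)]), `*`)
}

# brute-force Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(ord)]
}

# random orthogonal matrix (reflections allowed)
random_orthogonal <- function(k) {
  q <- qr.Q(qr(matrix(rnorm(k * k), k)))
  if (runif(1) < 0.5) q[, 1] <- -q[, 1]
  q
}

# aligned G1 asymmetry stack (subjects x parcels) for a cohort
ai_stack_g1 <- function(cohort, config, template, pattern = "intra") {
  subj <- names(cohort$subjects)
  t(vapply(subj, function(sid) {
    modes <- embed_all_modes(subject_connectome(cohort, sid), template,
                             config)
    if (pattern == "intra") modes$LL$scores[, 1] - modes$RR$scores[, 1]
    else modes$LR$scores[, 1] - modes$RL$scores[, 1]
  }, numeric(cohort$geometry$n_parcels)))
}
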