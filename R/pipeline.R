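# End-to-end orchestration: connectomes -> template -> per-subject aligned
# gradients -> asymmetry statistics -> heritability -> spin tests ->
# optional decoding, with provenance and deterministic outputs.

#' Pipeline run configuration
#'
#' @param embedding an [embedding_config()].
#' @param components_kept how many aligned gradients feed the asymmetry
#'   analyses (default 3: the principal, second and third gradients).
#' @param fdr_q FDR threshold used when reporting significant counts
#'   (default 0.05).
#' @param n_perm spin permutations (default 1000).
#' @param seed master seed for every stochastic stage.
#' @param include_joint also run the joint two-hemisphere embedding variant
#'   (default TRUE).
#' @param anchor optional orientation anchor map passed to
#'   [build_template()].
#' @param atlas optional `activation_atlas` to decode against the Cohen's d
#'   map of the principal gradient.
#' @param output_dir optional directory; when set, [write_tables()] is
#'   called on the result.
#' @return an object of class `run_config`.
#' @export
run_config <- function(embedding = embedding_config(), components_kept = 3L,
                       fdr_q = 0.05, n_perm = 1000L, seed = 1L,
                       include_joint = TRUE, anchor = NULL, atlas = NULL,
                       output_dir = NULL) {
  if (!inherits(embedding, "embedding_config"))
    fail("config error: embedding must be an embedding_config")
  if (components_kept < 1 || components_kept > embedding$n_components)
    fail("config error: components_kept must be in 1..n_components")
  if (fdr_q <= 0 || fdr_q >= 1) fail("config error: fdr_q must be in (0,1)")
  structure(list(embedding = embedding,
                 components_kept = as.integer(components_kept),
                 fdr_q = fdr_q, n_perm = as.integer(n_perm),
                 seed = as.integer(seed),
                 include_joint = isTRUE(include_joint),
                 anchor = anchor, atlas = atlas, output_dir = output_dir),
            class = "run_config")
}

#' Run the full asymmetry-gradient pipeline on a cohort
#'
#' Stages: session-averaged Fisher-z connectomes per subject; group-mean
#' reference connectome and sign-anchored gradient template; per-subject
#' diffusion embedding of all four modes with Procrustes alignment;
#' intra- (LL - RR) and inter-hemispheric (LR - RL) asymmetry indices for
#' the retained components with one-sample group statistics, BH-FDR and
#' Cohen's d; network-level summaries; parcel-wise AE heritability of the
#' principal-gradient asymmetry; a spin test between the intra and inter
#' mean-asymmetry maps; the normalized-AI variant; optionally the joint
#' two-hemisphere embedding and term decoding.
#'
#' @param cohort a `hemigrad_cohort` with time series, or a directory path
#'   readable by [read_cohort()].
#' @param config a [run_config()].
#' @return an object of class `hemigrad_run`; see [write_tables()] for the
#'   on-disk form.
#' @export
run_full_pipeline <- function(cohort, config = run_config()) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "hemigrad_cohort"))
  if (!length(cohort$subjects) || is.null(cohort$subjects[[1]]))
    fail("data error: cohort has no time series")
  ecfg <- config$embedding
  kk <- config$components_kept
  p <- cohort$geometry$n_parcels
  subjects <- names(cohort$subjects)
  n <- length(subjects)

  connectomes <- lapply(subjects, function(sid)
    subject_connectome(cohort, sid))
  names(connectomes) <- subjects
  tick("connectome")

  mean_ref <- group_mean_mode(connectomes, ecfg$reference_mode)
  template <- build_template(mean_ref, ecfg, anchor = config$anchor)
  tick("template")

  gl <- array(NA_real_, c(n, p, kk)); gr <- gl; glr <- gl; grl <- gl
  for (j in seq_len(n)) {
    modes <- embed_all_modes(connectomes[[j]], template, ecfg)
    gl[j, , ] <- modes$LL$scores[, seq_len(kk)]
    gr[j, , ] <- modes$RR$scores[, seq_len(kk)]
    glr[j, , ] <- modes$LR$scores[, seq_len(kk)]
    grl[j, , ] <- modes$RL$scores[, seq_len(kk)]
  }
  tick("embedding")

  ai <- list(intra = gl - gr, inter = glr - grl)
  shift <- list(intra = ai_shift_constant(gl, gr),
                inter = ai_shift_constant(glr, grl))
  ai_norm <- list(
    intra = normalized_asymmetry_index(gl, gr, shift = shift$intra),
    inter = normalized_asymmetry_index(glr, grl, shift = shift$inter))

  parcel_stats <- NULL
  network_stats <- NULL
  for (pat in c("intra", "inter")) {
    for (c in seq_len(kk)) {
      st <- group_asymmetry_stats(ai[[pat]][, , c])
      st$pattern <- pat; st$component <- paste0("G", c)
      parcel_stats <- rbind(parcel_stats, as.data.frame(st))
      ns <- network_summary(ai[[pat]][, , c], cohort$geometry$network)
      ns$pattern <- pat; ns$component <- paste0("G", c)
      network_stats <- rbind(network_stats, as.data.frame(ns))
    }
  }
  tick("asymmetry")

  herit <- heritability_map(ai$intra[, , 1], cohort$pedigree)
  tick("heritability")

  mean_ai_intra <- colMeans(ai$intra[, , 1])
  mean_ai_inter <- colMeans(ai$inter[, , 1])
  spin_intra_inter <- spin_corr_test(
    mean_ai_intra, mean_ai_inter, cohort$geometry$right,
    method = "spearman", n_perm = config$n_perm,
    seed = derive_seed(config$seed, "spin-intra-inter"))
  tick("spin")

  joint_ai <- NULL
  if (config$include_joint) {
    mean_joint <- group_mean_mode(connectomes, "joint")
    joint_anchor <- if (is.null(config$anchor)) NULL
                    else rep(config$anchor, 2)
    joint_template <- build_template(mean_joint, ecfg,
                                     anchor = joint_anchor)
    joint_ai <- array(NA_real_, c(n, p, kk))
    for (j in seq_len(n)) {
      gs <- embed_joint(connectomes[[j]], ecfg, template = joint_template)
      joint_ai[j, , ] <- gs$scores[seq_len(p), seq_len(kk)] -
        gs$scores[p + seq_len(p), seq_len(kk)]
    }
    tick("joint")
  }

  decoding <- NULL
  if (!is.null(config$atlas)) {
    d_map <- parcel_stats$cohens_d[parcel_stats$pattern == "intra" &
                                     parcel_stats$component == "G1"]
    decoding <- decode_terms(config$atlas, d_map)
    tick("decoding")
  }

  run <- structure(list(
    config = config,
    n_subjects = n,
    template = template,
    variance_explained = template$variance_explained,
    ai = ai, ai_norm = ai_norm, joint_ai = joint_ai,
    parcel_stats = parcel_stats, network_stats = network_stats,
    heritability = herit,
    spin_intra_inter = spin_intra_inter,
    decoding = decoding,
    timings = timings
  ), class = "hemigrad_run")
  if (!is.null(config$output_dir)) write_tables(run, config$output_dir)
  run
}

#' @export
print.hemigrad_run <- function(x, ...) {
  ve <- x$variance_explained[seq_len(min(3, length(x$variance_explained)))]
  cat("hemigrad_run:", x$n_subjects, "subjects\n")
  cat("  template variance explained:",
      paste0(sprintf("G%d %.1f%%", seq_along(ve), 100 * ve),
             collapse = ", "), "\n")
  sig <- with(x$parcel_stats,
              tapply(p_fdr < x$config$fdr_q, paste(pattern, component), sum))
  cat("  FDR-significant parcels:",
      paste(names(sig), sig, collapse = "; "), "\n")
  cat("  heritability of G1 intra AI: median h2 =",
      sprintf("%.2f", stats::median(x$heritability$h2)), "(",
      sum(x$heritability$p_fdr < x$config$fdr_q),
      "parcels P_FDR <", x$config$fdr_q, ")\n")
  cat("  intra vs inter mean-AI map: spearman r =",
      sprintf("%.3f", x$spin_intra_inter$r_observed),
      ", P_spin =", sprintf("%.4g", x$spin_intra_inter$p_spin), "\n")
  invisible(x)
}

#' Write the pipeline result bundle as delimited tables with a manifest
#'
#' Numeric tables are deterministic given the run configuration and seed;
#' the manifest and log (which carry wall-clock timings) are written
#' separately so the tables themselves are bit-reproducible.
#'
#' @param run a `hemigrad_run`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_tables <- function(run, dir) {
  stopifnot(inherits(run, "hemigrad_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, name)
    utils::write.csv(format(df, digits = 12, scientific = FALSE,
                            trim = TRUE),
                     file.path(dir, name), row.names = FALSE, quote = FALSE)
  wr(run$parcel_stats, "parcel_stats.csv")
  wr(run$network_stats, "network_stats.csv")
  wr(run$heritability, "heritability.csv")
  wr(data.frame(component = paste0("G", seq_along(run$variance_explained)),
                eigenvalue = run$template$eigenvalues,
                variance_explained = run$variance_explained),
     "variance_explained.csv")
  if (!is.null(run$decoding)) wr(run$decoding, "decoding.csv")

  cfg <- run$config
  cfg_json <- jsonlite::toJSON(list(
    embedding = unclass(cfg$embedding),
    components_kept = cfg$components_kept, fdr_q = cfg$fdr_q,
    n_perm = cfg$n_perm, seed = cfg$seed,
    include_joint = cfg$include_joint,
    has_anchor = !is.null(cfg$anchor), has_atlas = !is.null(cfg$atlas)
  ), auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package_version = as.character(utils::packageVersion("hemigrad")),
    r_version = R.version.string,
    seed = cfg$seed,
    config = jsonlite::fromJSON(cfg_json),
    config_hash = derive_seed(0L, as.character(cfg_json)),
    n_subjects = run$n_subjects,
    timings_sec = as.list(run$timings)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
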