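# Twin-structured synthetic cohort generator.  Produces parcellated time
# series whose functional connectivity encodes a smooth latent gradient with
# a heritable, spatially patterned left-right shift, plus the pedigree and
# ground truth needed for recovery tests.

# Total SD of the per-subject asymmetry shift around its unit mean.  The
# shift s_j = 1 + g_j + e_j has population mean 1 (so a nonzero group-mean
# asymmetry exists to recover) and variance SHIFT_SD^2 split between the
# additive-genetic part g and the unique-environment part e according to
# h2_target.
SHIFT_SD <- 0.6

#' Specification of a synthetic twin cohort
#'
#' Bundles and validates the generator parameters.  Defaults describe a
#' small desk-scale cohort: 30 monozygotic (MZ) and 30 dizygotic (DZ) twin
#' pairs plus 10 singletons (130 subjects), 60 parcels per hemisphere, and
#' four sessions of 300 timepoints per subject (mirroring a four-session
#' resting-state design at reduced length).
#'
#' @param n_mz_pairs,n_dz_pairs,n_singletons family-structure counts
#'   (pairs >= 1, singletons >= 0).
#' @param n_parcels_per_hemisphere parcels per hemisphere (>= 4).
#' @param n_timepoints samples per session (>= 2).
#' @param n_sessions sessions per subject.
#' @param h2_target narrow-sense heritability of the subject-level
#'   asymmetry shift, in [0, 1].
#' @param asym_scale magnitude of the left-right latent shift; 0 gives a
#'   perfectly symmetric (null) cohort.
#' @param noise_sd SD of additive measurement noise on the time series
#'   (signal parts have unit variance).
#' @param n_basis_signals number of shared latent basis signals mixed into
#'   each parcel's series.
#' @param kernel_width Gaussian mixing-kernel width on the latent axis
#'   (latent-axis units).
#' @param seed integer master seed; every derived artifact records it.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_mz_pairs = 30L, n_dz_pairs = 30L,
                        n_singletons = 10L,
                        n_parcels_per_hemisphere = 60L,
                        n_timepoints = 300L, n_sessions = 4L,
                        h2_target = 0.5, asym_scale = 0.1,
                        noise_sd = 1, n_basis_signals = 12L,
                        kernel_width = 0.2, seed = 1L) {
  counts <- c(n_mz_pairs = n_mz_pairs, n_dz_pairs = n_dz_pairs,
              n_parcels_per_hemisphere = n_parcels_per_hemisphere,
              n_timepoints = n_timepoints, n_sessions = n_sessions,
              n_basis_signals = n_basis_signals)
  if (any(counts < 1))
    fail("invalid cohort spec: ", paste(names(counts)[counts < 1],
                                        collapse = ", "), " must be >= 1")
  if (n_singletons < 0)
    fail("invalid cohort spec: n_singletons must be >= 0")
  if (!is.numeric(h2_target) || h2_target < 0 || h2_target > 1)
    fail("invalid cohort spec: h2_target must lie in [0, 1]")
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    fail("invalid cohort spec: noise_sd must be > 0")
  if (n_timepoints < 2)
    fail("invalid cohort spec: n_timepoints must be >= 2")
  structure(list(
    n_mz_pairs = as.integer(n_mz_pairs),
    n_dz_pairs = as.integer(n_dz_pairs),
    n_singletons = as.integer(n_singletons),
    n_parcels_per_hemisphere = as.integer(n_parcels_per_hemisphere),
    n_timepoints = as.integer(n_timepoints),
    n_sessions = as.integer(n_sessions),
    h2_target = h2_target, asym_scale = asym_scale,
    noise_sd = noise_sd, n_basis_signals = as.integer(n_basis_signals),
    kernel_width = kernel_width, seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  n <- 2L * (x$n_mz_pairs + x$n_dz_pairs) + x$n_singletons
  cat("cohort_spec:", n, "subjects (", x$n_mz_pairs, "MZ +", x$n_dz_pairs,
      "DZ pairs +", x$n_singletons, "singletons ),",
      x$n_parcels_per_hemisphere, "parcels/hemisphere,", x$n_sessions,
      "x", x$n_timepoints, "timepoints\n")
  cat("  h2_target =", x$h2_target, " asym_scale =", x$asym_scale,
      " noise_sd =", x$noise_sd, " seed =", x$seed, "\n")
  invisible(x)
}

# Pedigree skeleton matching the spec counts: MZ families, DZ families,
# singleton families, in that order.  Ages and sexes are drawn to be usable
# as covariates; co-twins share age.
make_pedigree <- function(spec) {
  with_seed(derive_seed(spec$seed, "pedigree"), {
    fam_mz <- seq_len(spec$n_mz_pairs)
    fam_dz <- spec$n_mz_pairs + seq_len(spec$n_dz_pairs)
    fam_sg <- spec$n_mz_pairs + spec$n_dz_pairs + seq_len(spec$n_singletons)
    family_id <- c(rep(fam_mz, each = 2), rep(fam_dz, each = 2), fam_sg)
    zygosity <- c(rep("MZ", 2 * spec$n_mz_pairs),
                  rep("DZ", 2 * spec$n_dz_pairs),
                  rep("SINGLETON", spec$n_singletons))
    n <- length(family_id)
    fam_age <- round(stats::runif(max(family_id), 22, 36), 1)
    data.frame(
      subject_id = sprintf("sub-%04d", seq_len(n)),
      family_id = sprintf("fam-%04d", family_id),
      zygosity = zygosity,
      age = fam_age[family_id],
      sex = stats::rbinom(n, 1, 0.5),
      stringsAsFactors = FALSE
    )
  })
}

# Per-subject asymmetry shifts s = 1 + g + e honouring the twin structure:
# MZ co-twins share g exactly, DZ co-twins' g correlates 0.5, singletons are
# independent; var(g) = h2 * SHIFT_SD^2, var(e) = (1 - h2) * SHIFT_SD^2.
make_subject_shifts <- function(spec, pedigree) {
  h2 <- spec$h2_target
  sd_g <- SHIFT_SD * sqrt(h2)
  sd_e <- SHIFT_SD * sqrt(1 - h2)
  with_seed(derive_seed(spec$seed, "shifts"), {
    n <- nrow(pedigree)
    g <- numeric(n)
    for (fam in unique(pedigree$family_id)) {
      idx <- which(pedigree$family_id == fam)
      zyg <- pedigree$zygosity[idx[1]]
      if (zyg == "MZ") {
        g[idx] <- stats::rnorm(1, 0, sd_g)
      } else if (zyg == "DZ") {
        shared <- stats::rnorm(1, 0, sd_g / sqrt(2))
        g[idx] <- shared + stats::rnorm(2, 0, sd_g / sqrt(2))
      } else {
        g[idx] <- stats::rnorm(length(idx), 0, sd_g)
      }
    }
    e <- stats::rnorm(n, 0, sd_e)
    list(g = g, e = e, s = 1 + g + e)
  })
}

# Smooth-in-time standardised basis signals, one matrix per call
# (n_basis x n_timepoints).
make_basis_signals <- function(n_basis, n_timepoints) {
  raw <- matrix(stats::rnorm(n_basis * (n_timepoints + 8)), n_basis)
  win <- stats::dnorm(-4:4, sd = 1.5)
  sm <- t(apply(raw, 1, function(row)
    stats::convolve(row, win, type = "filter")))
  sm <- sm[, seq_len(n_timepoints), drop = FALSE]
  t(scale(t(sm)))
}

# Mixing weights of parcels (rows, at latent positions x) onto the shared
# basis signals: local Gaussian-kernel weights onto the basis centres plus
# one global axis signal whose loading is linear in latent position.  The
# global component mimics the core long-range axis structure of real
# functional connectivity and gives the embedding a dominant principal
# gradient; the local kernel gives smooth banded structure around it.
# Rows are scaled to unit L2 norm so every parcel's signal part has unit
# variance.
AXIS_LOADING <- 1.5

mixing_weights <- function(x, centres, width) {
  w <- exp(-outer(x, centres, "-")^2 / (2 * width^2))
  w <- w / sqrt(rowSums(w^2))
  w <- cbind(w, AXIS_LOADING * (x - 0.5))
  w / sqrt(rowSums(w^2))
}

#' Generate a synthetic twin cohort of parcellated time series
#'
#' Simulates, for every subject, hemisphere and session, a parcels x
#' timepoints matrix in which parcel i mixes shared smooth basis signals
#' with Gaussian-kernel weights centred on the parcel's latent position,
#' plus white measurement noise.  The left/right latent positions of
#' subject j are shifted apart by `asym_scale * delta_i * s_j / 2` in
#' opposite directions, where `delta` is a smooth spatial asymmetry field
#' (positive = leftward; by default organised along the latent axis, see
#' Details in the source) and `s_j = 1 + g_j + e_j` is the subject's
#' heritable asymmetry shift.  Functional connectivity computed from these
#' series therefore carries a gradient whose left-right difference has a
#' known spatial pattern and a known heritability.
#'
#' @param spec a [cohort_spec()].
#' @param geometry optional [make_parcel_geometry()] result to reuse;
#'   default derives one from the spec seed.
#' @param asym_field optional per-parcel asymmetry field to impose instead
#'   of the generated smooth field (used for coupled species pairs).
#' @param generate_timeseries set `FALSE` to skip the (relatively costly)
#'   time-series synthesis and return only pedigree, geometry and ground
#'   truth.
#' @return an object of class `hemigrad_cohort`: list with `spec`,
#'   `geometry`, `pedigree`, `ground_truth` (latent positions, asymmetry
#'   field, subject shifts and their genetic/environmental parts) and
#'   `subjects` (per subject, per session, matrices `L` and `R`).
#' @export
make_timeseries_cohort <- function(spec, geometry = NULL, asym_field = NULL,
                                   generate_timeseries = TRUE) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  p <- spec$n_parcels_per_hemisphere
  if (is.null(geometry))
    geometry <- make_parcel_geometry(p, seed = derive_seed(spec$seed, "geom"))
  if (geometry$n_parcels != p)
    fail("geometry has ", geometry$n_parcels, " parcels but spec asks for ", p)
  # Default asymmetry field: organised along the latent functional axis,
  # leftward at the low-latent pole and rightward at the high-latent pole
  # (standardised cos(pi * latent)).  This mirrors the empirical picture of
  # gradient asymmetry -- language/default regions at one end of the
  # principal axis lateralise opposite to frontoparietal regions at the
  # other -- and plants the pattern in the subspace that aligned-gradient
  # differencing can attribute (shift patterns confounded with a uniform
  # translation or affine stretch of the axis are not identifiable from
  # aligned scores).  A custom field can be injected for other designs.
  delta <- if (is.null(asym_field))
    as.vector(scale(cos(pi * geometry$latent)))
  else as.numeric(asym_field)
  if (length(delta) != p) fail("asym_field must have one value per parcel")

  pedigree <- make_pedigree(spec)
  shifts <- make_subject_shifts(spec, pedigree)
  n <- nrow(pedigree)

  centres <- seq(0, 1, length.out = spec$n_basis_signals)
  subjects <- vector("list", n)
  names(subjects) <- pedigree$subject_id
  if (generate_timeseries) {
    for (j in seq_len(n)) {
      off <- 0.5 * spec$asym_scale * delta * shifts$s[j]
      x_left <- geometry$latent + off
      x_right <- geometry$latent - off
      w_left <- mixing_weights(x_left, centres, spec$kernel_width)
      w_right <- mixing_weights(x_right, centres, spec$kernel_width)
      sessions <- vector("list", spec$n_sessions)
      for (c in seq_len(spec$n_sessions)) {
        sessions[[c]] <- with_seed(
          derive_seed(spec$seed, "ts", j, c), {
            b <- make_basis_signals(spec$n_basis_signals + 1L,
                                    spec$n_timepoints)
            list(
              L = w_left %*% b +
                spec$noise_sd * matrix(stats::rnorm(p * spec$n_timepoints), p),
              R = w_right %*% b +
                spec$noise_sd * matrix(stats::rnorm(p * spec$n_timepoints), p)
            )
          })
      }
      subjects[[j]] <- sessions
    }
  }

  structure(list(
    spec = spec,
    geometry = geometry,
    pedigree = pedigree,
    ground_truth = list(
      latent_positions = geometry$latent,
      asym_field = delta,
      subject_shift = shifts$s,
      genetic = shifts$g,
      environmental = shifts$e,
      shift_sd = SHIFT_SD,
      sphere_coords = list(left = geometry$left, right = geometry$right),
      seed = spec$seed
    ),
    subjects = subjects
  ), class = "hemigrad_cohort")
}

#' @export
print.hemigrad_cohort <- function(x, ...) {
  cat("hemigrad_cohort:", nrow(x$pedigree), "subjects,",
      x$spec$n_parcels_per_hemisphere, "parcels/hemisphere,",
      x$spec$n_sessions, "session(s)",
      if (length(x$subjects) && !is.null(x$subjects[[1]]))
        "(time series present)" else "(ground truth only)", "\n")
  invisible(x)
}

#' Write a cohort to a directory of delimited text files
#'
#' Layout: one whitespace-delimited parcels x timepoints matrix per
#' subject/hemisphere/session (`<subject>_<L|R>_ses-<k>.tsv`),
#' `pedigree.csv`, `geometry.csv` and `ground_truth.json`.  Numeric values
#' are written with \%.12g precision, which round-trips the analysis
#' losslessly at that precision.
#'
#' @param cohort a `hemigrad_cohort` with time series present.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "hemigrad_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(m) apply(m, 1, function(r) paste(sprintf("%.12g", r),
                                                   collapse = "\t"))
  for (sid in names(cohort$subjects)) {
    sess <- cohort$subjects[[sid]]
    for (k in seq_along(sess)) {
      for (h in c("L", "R")) {
        f <- file.path(dir, sprintf("%s_%s_ses-%d.tsv", sid, h, k))
        writeLines(fmt(sess[[k]][[h]]), f)
      }
    }
  }
  utils::write.csv(cohort$pedigree, file.path(dir, "pedigree.csv"),
                   row.names = FALSE)
  utils::write.csv(geometry_table(cohort$geometry),
                   file.path(dir, "geometry.csv"), row.names = FALSE)
  gt <- cohort$ground_truth
  jsonlite::write_json(
    list(latent_positions = gt$latent_positions,
         asym_field = gt$asym_field,
         subject_shift = gt$subject_shift,
         genetic = gt$genetic, environmental = gt$environmental,
         shift_sd = gt$shift_sd, seed = gt$seed,
         spec = unclass(cohort$spec)),
    file.path(dir, "ground_truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' Validates the layout strictly: a missing pedigree column, a subject with
#' inconsistent parcel counts, or an empty directory raise named errors
#' rather than silent skips.
#'
#' @param dir cohort directory.
#' @return a `hemigrad_cohort` (without generator spec unless
#'   `ground_truth.json` is present).
#' @export
read_cohort <- function(dir) {
  if (!dir.exists(dir)) fail("cohort directory not found: ", dir)
  ped_file <- file.path(dir, "pedigree.csv")
  if (!file.exists(ped_file)) fail("no pedigree.csv in ", dir)
  pedigree <- utils::read.csv(ped_file, stringsAsFactors = FALSE)
  need <- c("subject_id", "family_id", "zygosity", "age", "sex")
  miss <- setdiff(need, names(pedigree))
  if (length(miss))
    fail("pedigree.csv is missing column(s): ", paste(miss, collapse = ", "))
  geom <- geometry_from_table(
    utils::read.csv(file.path(dir, "geometry.csv"), stringsAsFactors = FALSE))

  files <- list.files(dir, pattern = "_ses-[0-9]+\\.tsv$")
  if (!length(files)) fail("no subjects found in ", dir)
  subjects <- list()
  for (sid in pedigree$subject_id) {
    sf <- sort(files[startsWith(files, paste0(sid, "_"))])
    ks <- sort(unique(as.integer(sub(".*_ses-([0-9]+)\\.tsv$", "\\1", sf))))
    if (!length(ks)) fail("no time-series files for subject ", sid)
    sess <- lapply(ks, function(k) {
      read_mat <- function(h) {
        f <- file.path(dir, sprintf("%s_%s_ses-%d.tsv", sid, h, k))
        if (!file.exists(f)) fail("missing file: ", f)
        m <- as.matrix(utils::read.table(f))
        dimnames(m) <- NULL
        if (nrow(m) != geom$n_parcels)
          fail(f, ": expected ", geom$n_parcels, " parcel rows, found ",
               nrow(m))
        m
      }
      list(L = read_mat("L"), R = read_mat("R"))
    })
    subjects[[sid]] <- sess
  }

  gt <- NULL
  spec <- NULL
  gt_file <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_file)) {
    gj <- jsonlite::read_json(gt_file, simplifyVector = TRUE)
    spec <- do.call(cohort_spec, gj$spec)
    gt <- list(latent_positions = gj$latent_positions,
               asym_field = gj$asym_field,
               subject_shift = gj$subject_shift,
               genetic = gj$genetic, environmental = gj$environmental,
               shift_sd = gj$shift_sd,
               sphere_coords = list(left = geom$left, right = geom$right),
               seed = gj$seed)
  }
  structure(list(spec = spec, geometry = geom, pedigree = pedigree,
                 ground_truth = gt, subjects = subjects),
            class = "hemigrad_cohort")
}
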