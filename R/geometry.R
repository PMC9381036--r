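# Parcel geometry: homologous spherical centroids for two hemispheres plus
# the latent functional axis that the synthetic cohorts encode.

#' Generate mirrored parcel centroids on a spherical hemisphere
#'
#' Places `n_parcels` centroids roughly evenly over the right hemisphere of
#' the unit sphere (the half-space x > 0) using a Fibonacci spiral mapped
#' through the inverse Lambert equal-area projection, then mirrors them
#' across the midline plane x = 0 to obtain homologous left-hemisphere
#' centroids.  A seed-dependent rotation about the x axis (which commutes
#' with the mirror) randomises the layout while preserving exact
#' left/right homology.
#'
#' The latent position of each parcel is a monotone (quantile) transform
#' of the z coordinate, scaled to [0, 1].  It plays the
#' role of the principal functional axis (unimodal to transmodal) that the
#' connectivity simulator organises time series along, and is identical for
#' homologous parcels.  Parcels are also partitioned into `n_networks`
#' contiguous bands of the latent axis, standing in for a functional network
#' atlas.
#'
#' @param n_parcels number of parcels per hemisphere (>= 4).
#' @param seed integer seed controlling the layout rotation.
#' @param n_networks number of latent-axis bands used as network labels
#'   (default 12).
#' @return an object of class `parcel_geometry`: a list with unit-row
#'   matrices `left` and `right` (n x 3), the shared `latent` vector in
#'   [0, 1], and a `network` factor.
#' @examples
#' g <- make_parcel_geometry(60, seed = 1)
#' range(rowSums(g$right^2))  # unit norm
#' @export
make_parcel_geometry <- function(n_parcels, seed = 1L, n_networks = 12L) {
  if (!is.numeric(n_parcels) || n_parcels < 4)
    fail("invalid geometry spec: n_parcels must be >= 4")
  n <- as.integer(n_parcels)

  # Fibonacci spiral on a disk of radius sqrt(2), lifted to the hemisphere
  # about +x by the inverse Lambert azimuthal equal-area projection.
  k <- seq_len(n)
  golden <- pi * (3 - sqrt(5))
  rho <- sqrt(2 * (k - 0.5) / n)
  theta <- golden * k
  px <- 1 - rho^2 / 2
  scale_yz <- sqrt(pmax(1 - rho^2 / 4, 0))
  py <- scale_yz * rho * cos(theta)
  pz <- scale_yz * rho * sin(theta)

  # random rotation about the mirror axis: keeps homology exact
  ang <- with_seed(derive_seed(seed, "geometry-rotation"),
                   stats::runif(1, 0, 2 * pi))
  y2 <- cos(ang) * py - sin(ang) * pz
  z2 <- sin(ang) * py + cos(ang) * pz

  right <- cbind(x = px, y = y2, z = z2)
  left <- right
  left[, 1] <- -left[, 1]

  # monotone quantile transform of z: keeps the latent axis spatial and
  # ordered while giving parcels uniform density along it, so the principal
  # diffusion axis of a smooth connectivity kernel is ~linear in latent
  latent <- (rank(z2) - 0.5) / n
  network <- factor(paste0("N", as.integer(cut(latent, n_networks,
                                               labels = FALSE))),
                    levels = paste0("N", seq_len(n_networks)))

  structure(list(left = left, right = right, latent = latent,
                 network = network, n_parcels = n, seed = seed),
            class = "parcel_geometry")
}

#' @export
print.parcel_geometry <- function(x, ...) {
  cat("parcel_geometry:", x$n_parcels, "parcels per hemisphere,",
      nlevels(x$network), "latent-axis networks (seed", paste0(x$seed, ")\n"))
  invisible(x)
}

# Long-format table used for on-disk round trips.
geometry_table <- function(geom) {
  n <- geom$n_parcels
  data.frame(
    parcel = rep(seq_len(n), 2L),
    hemisphere = rep(c("L", "R"), each = n),
    x = c(geom$left[, 1], geom$right[, 1]),
    y = c(geom$left[, 2], geom$right[, 2]),
    z = c(geom$left[, 3], geom$right[, 3]),
    latent = rep(geom$latent, 2L),
    network = rep(as.character(geom$network), 2L),
    stringsAsFactors = FALSE
  )
}

geometry_from_table <- function(tab) {
  need <- c("parcel", "hemisphere", "x", "y", "z", "latent", "network")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    fail("geometry table is missing column(s): ", paste(miss, collapse = ", "))
  l <- tab[tab$hemisphere == "L", ]
  r <- tab[tab$hemisphere == "R", ]
  l <- l[order(l$parcel), ]
  r <- r[order(r$parcel), ]
  structure(list(
    left = cbind(x = l$x, y = l$y, z = l$z),
    right = cbind(x = r$x, y = r$y, z = r$z),
    latent = r$latent,
    network = factor(r$network, levels = unique(r$network[order(r$latent)])),
    n_parcels = nrow(r), seed = NA_integer_
  ), class = "parcel_geometry")
}
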