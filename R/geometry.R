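#' Membrane lattice geometry with ER-PM junctions
#'
#' Defines the square plasma-membrane patch on which the stochastic simulator
#' runs: a lattice of subvolumes of side `lattice_spacing`, with reflective
#' boundaries, and a set of circular ER-PM junction footprints where clustered
#' STIM1 can trap Orai1 dimers.
#'
#' Junction disks must lie fully inside the domain and may not overlap. By
#' default junction centers are placed deterministically on a regular grid
#' (snapped to subvolume centers) so that a geometry is fully reproducible
#' without consuming random numbers.
#'
#' @param domain_side Side length of the square membrane patch (um).
#' @param lattice_spacing Subvolume side `h` (um); must divide `domain_side`
#'   into a whole number of subvolumes.
#' @param n_junctions Number of ER-PM junctions (ignored when `centers` given).
#' @param junction_radius Radius of each junction disk (um).
#' @param centers Optional two-column matrix of junction centers (um). When
#'   `NULL`, centers are placed on a regular grid.
#' @return An object of class `socm_geometry`: list with `domain_side`, `h`,
#'   `nx`, `ny`, `junctions` (data frame `x`, `y`, `radius`), and the derived
#'   lattice maps `junction_of` (subvolume -> junction id, 0 = bulk) and
#'   `junction_svs` (list of subvolume indices per junction).
#' @examples
#' g <- socm_geometry(domain_side = 5, n_junctions = 8)
#' g
#' @export
socm_geometry <- function(domain_side = 10, lattice_spacing = 0.2,
                          n_junctions = 20, junction_radius = 0.1,
                          centers = NULL) {
  h <- lattice_spacing
  if (!is.numeric(h) || h <= 0) stop("lattice_spacing must be > 0")
  n_side <- domain_side / h
  if (abs(n_side - round(n_side)) > 1e-8)
    stop("domain_side must be an integer multiple of lattice_spacing")
  nx <- ny <- as.integer(round(n_side))

  if (is.null(centers)) {
    centers <- junction_grid_centers(domain_side, h, n_junctions, junction_radius)
  } else {
    centers <- as.matrix(centers)
    if (ncol(centers) != 2) stop("centers must be a 2-column matrix")
  }
  nj <- nrow(centers)
  r <- junction_radius
  if (nj > 0) {
    inside <- centers[, 1] - r >= 0 & centers[, 1] + r <= domain_side &
      centers[, 2] - r >= 0 & centers[, 2] + r <= domain_side
    if (!all(inside)) stop("every junction disk must lie fully inside the domain")
    if (nj > 1) {
      dd <- as.matrix(stats::dist(centers))
      diag(dd) <- Inf
      if (any(dd < 2 * r)) stop("junction disks may not overlap")
    }
  }

  # subvolume membership: center of sv within junction radius
  cx <- (seq_len(nx) - 0.5) * h
  cy <- (seq_len(ny) - 0.5) * h
  junction_of <- integer(nx * ny)
  junction_svs <- vector("list", nj)
  for (j in seq_len(nj)) {
    d2 <- outer((cx - centers[j, 1])^2, (cy - centers[j, 2])^2, "+")
    svs <- which(d2 <= r^2)  # column-major: sv = x + nx*(y-1)
    if (length(svs) == 0)
      stop("junction ", j, " covers no subvolume; increase radius or spacing")
    if (any(junction_of[svs] != 0))
      stop("junction subvolume footprints overlap")
    junction_of[svs] <- j
    junction_svs[[j]] <- svs
  }

  structure(list(
    domain_side = domain_side, h = h, nx = nx, ny = ny,
    junctions = data.frame(x = centers[, 1], y = centers[, 2],
                           radius = rep(r, nj)),
    junction_of = junction_of, junction_svs = junction_svs
  ), class = "socm_geometry")
}

# deterministic near-square grid of junction centers, snapped to sv centers
junction_grid_centers <- function(domain_side, h, n, radius) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  ncol_g <- ceiling(sqrt(n))
  nrow_g <- ceiling(n / ncol_g)
  xs <- domain_side * (seq_len(ncol_g) - 0.5) / ncol_g
  ys <- domain_side * (seq_len(nrow_g) - 0.5) / nrow_g
  snap <- function(v) (round(v / h - 0.5) + 0.5) * h
  grid <- expand.grid(x = snap(xs), y = snap(ys))
  as.matrix(grid[seq_len(n), , drop = FALSE])
}

#' @export
print.socm_geometry <- function(x, ...) {
  cat(sprintf("Membrane lattice: %.3g x %.3g um, h = %.3g um (%d x %d subvolumes)\n",
              x$domain_side, x$domain_side, x$h, x$nx, x$ny))
  cat(sprintf("Junctions: %d disks of radius %.3g um (%d subvolumes total)\n",
              nrow(x$junctions),
              if (nrow(x$junctions)) x$junctions$radius[1] else NA_real_,
              sum(x$junction_of != 0)))
  invisible(x)
}

#' Reduced-size default geometry
#'
#' A smaller membrane patch (5 um side, 8 junctions) with the same subvolume
#' size and junction radius as [socm_geometry()] defaults. Used for parameter
#' sweeps where many replicate trajectories are needed.
#'
#' @return A `socm_geometry` object.
#' @export
socm_geometry_reduced <- function() {
  socm_geometry(domain_side = 5, lattice_spacing = 0.2,
                n_junctions = 8, junction_radius = 0.1)
}
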