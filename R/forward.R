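#' Forward 1-D Poisson solver
#'
#' Maps a depth-by-time current source density grid to extracellular
#' potentials at the probe contacts under the same assumptions the
#' second-difference CSD estimator makes: currents flow parallel to the
#' probe axis and tissue conductivity is spatially homogeneous. Per time
#' sample it solves
#'
#' `d2(phi)/dz2 = -C(z, t) / sigma`
#'
#' with zero-potential (Dirichlet) boundaries at the extended grid edges
#' (far-field assumption), then samples `phi` at the contact depths.
#'
#' @param csd_profile A `density_grid` from [build_evoked_density()], or any
#'   list with `density` (depth x time), `depths_um` (uniform, at least 4x
#'   finer than the contact spacing, extending >= 500 um beyond the first and
#'   last contact).
#' @param geometry A [probe_geometry()].
#' @param conductivity Scalar conductivity sigma (> 0). Output is in
#'   arbitrary-unit-consistent mV when densities are in arbitrary units.
#' @return A channels x time matrix of potentials at the contact depths.
#' @export
solve_forward <- function(csd_profile, geometry, conductivity = 1) {
  stopifnot(conductivity > 0)
  z <- csd_profile$depths_um
  C <- csd_profile$density
  if (!all(is.finite(C))) stop("non-finite densities in csd_profile")
  dzv <- diff(z)
  if (any(abs(dzv - dzv[1]) > 1e-9)) stop("depth grid must be uniform")
  dz <- dzv[1]
  d <- contact_depths(geometry)
  if (dz > geometry$spacing_um / 4 + 1e-9)
    stop("geometry error: density grid must be at least 4x finer than the contact spacing")
  if (z[1] > d[1] - 500 + 1e-9 || z[length(z)] < d[length(d)] + 500 - 1e-9)
    stop("geometry error: density grid must extend >= 500 um beyond the probe ends")

  n <- length(z)
  ni <- n - 2L # interior nodes (Dirichlet: phi = 0 at both edges)
  A <- Matrix::bandSparse(ni, ni, k = -1:1,
                          diagonals = list(rep(1, ni - 1), rep(-2, ni),
                                           rep(1, ni - 1)))
  rhs <- -C[2:(n - 1), , drop = FALSE] * dz^2 / conductivity
  phi_i <- as.matrix(Matrix::solve(A, rhs))
  phi <- rbind(0, phi_i, 0)

  # sample at contact depths (linear interpolation between grid nodes;
  # exact when contacts coincide with nodes, as fine_depth_grid guarantees)
  idx <- findInterval(d, z, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), n - 1L)
  w <- (d - z[idx]) / dz
  phi[idx, , drop = FALSE] * (1 - w) + phi[idx + 1L, , drop = FALSE] * w
}
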