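#' Linear probe geometry
#'
#' Describes a linear multi-electrode array spanning the CA1-dentate gyrus
#' axis: either 16 contacts at 100 um or 32 contacts at 50 um pitch in the
#' default configurations. Channel 1 is the most dorsal contact and depth
#' increases with channel index.
#'
#' @param n_contacts Number of recording contacts (>= 3).
#' @param spacing_um Inter-contact spacing in micrometres (> 0).
#' @param depth_of_first_contact_um Depth of the most dorsal contact, um.
#' @return An object of class `probe_geometry` with element `depths_um`,
#'   the strictly increasing contact depths.
#' @examples
#' geom <- probe_geometry()
#' contact_depths(geom)[1:4]
#' @export
probe_geometry <- function(n_contacts = 16, spacing_um = 100,
                           depth_of_first_contact_um = 1100) {
  stopifnot(is.numeric(n_contacts), length(n_contacts) == 1L, n_contacts >= 3,
            is.numeric(spacing_um), length(spacing_um) == 1L, spacing_um > 0,
            is.numeric(depth_of_first_contact_um),
            length(depth_of_first_contact_um) == 1L)
  n_contacts <- as.integer(n_contacts)
  g <- list(
    n_contacts = n_contacts,
    spacing_um = spacing_um,
    depth_of_first_contact_um = depth_of_first_contact_um,
    depths_um = depth_of_first_contact_um + spacing_um * (seq_len(n_contacts) - 1)
  )
  class(g) <- "probe_geometry"
  g
}

#' @export
print.probe_geometry <- function(x, ...) {
  cat(sprintf("<probe_geometry> %d contacts, %g um pitch, depths %g-%g um\n",
              x$n_contacts, x$spacing_um, min(x$depths_um), max(x$depths_um)))
  invisible(x)
}

#' Contact depths of a probe
#' @param geometry A [probe_geometry()].
#' @return Numeric vector of contact depths (um), dorsal to ventral.
#' @export
contact_depths <- function(geometry) {
  stopifnot(inherits(geometry, "probe_geometry"))
  geometry$depths_um
}
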