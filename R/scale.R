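#' Voxel-to-cell scale parameters
#'
#' The simulation runs at a driver mutation rate \code{mu} about 100 times
#' the empirical per-division rate \code{mu_real}; each 2D voxel therefore
#' stands for \code{mu / mu_real} identical cells, and one voxel edge for
#' \code{sqrt(mu / mu_real)} cell diameters.
#'
#' @param mu simulated driver mutation rate (0.001).
#' @param mu_real empirical driver mutation rate (1e-5).
#' @param cell_diameter_um tumor cell diameter in micrometers (20).
#' @return Object of class \code{"scale_params"} with the derived
#'   \code{cells_per_voxel} (100 at defaults).
#' @export
scale_params <- function(mu = 0.001, mu_real = 1e-5, cell_diameter_um = 20) {
  stopifnot(mu > 0, mu_real > 0, cell_diameter_um > 0)
  sp <- list(mu = mu, mu_real = mu_real,
             cells_per_voxel = mu / mu_real,
             cell_diameter_um = cell_diameter_um)
  class(sp) <- "scale_params"
  sp
}

#' Equivalent 3D tumor population of a 2D voxel count
#'
#' The 2D simulation is read as a cross-section of a 3D tumor: a sphere
#' whose cross-sectional area equals the simulated cell area gives
#' \deqn{N = \frac{4}{3}\pi \left(\sqrt{\frac{\mu}{\mu_{real}} \frac{m}{\pi}}\right)^3.}
#' A disc of radius 90 voxels (25,447 voxels) maps to about 3 billion
#' cells; 60,000 voxels to about 10 billion.
#'
#' @param m voxel count (vectorized).
#' @param sp a [scale_params()] object.
#' @return Equivalent 3D cell count.
#' @export
voxels_to_3d_population <- function(m, sp = scale_params()) {
  stopifnot(all(m >= 0))
  (4 / 3) * pi * sqrt(sp$cells_per_voxel * m / pi)^3
}

#' Physical radius of a voxel radius
#'
#' One voxel edge is \code{sqrt(cells_per_voxel)} cell diameters, so a
#' radius of R voxels corresponds to
#' \code{R * sqrt(cells_per_voxel) * cell_diameter} (0.4 cm at R = 20,
#' 1.2 cm at R = 60, with the defaults).
#'
#' @param R_voxels radius in voxels (vectorized).
#' @param sp a [scale_params()] object.
#' @return Radius in centimeters.
#' @export
voxel_radius_to_cm <- function(R_voxels, sp = scale_params()) {
  stopifnot(all(R_voxels >= 0))
  R_voxels * sqrt(sp$cells_per_voxel) * sp$cell_diameter_um * 1e-4
}
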