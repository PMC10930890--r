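#' Simulation parameters for the lattice tumor model
#'
#' Bundles and validates all knobs of the boundary-driven growth model:
#' baseline birth probability \code{b}, driver selective advantage \code{s},
#' Poisson driver mutation rate \code{mu} per division, core (sanctuary)
#' death probability \code{d1}, edge death probability \code{d2}, sanctuary
#' radius \code{R} in voxels, the detection radius, the terminal voxel count,
#' and the growth/selection model variants.
#'
#' The death-rate split between core and edge only applies after the tumor is
#' detected (occupied voxels reaching the area of a disc of
#' \code{detection_radius}); before detection every cell experiences
#' \code{d1}. The parameter regime is classified as \emph{driver-dependent}
#' invasion when \code{d1 < b < d2} (only clones with enough drivers can
#' expand at the edge) and \emph{driver-independent} when \code{d1 < d2 < b}.
#'
#' @param b baseline per-event division probability (default 0.7).
#' @param s multiplicative selective advantage per driver mutation (0.1).
#' @param mu Poisson driver mutation rate per division (0.001).
#' @param d1 death probability in the core / sanctuary site (0.1).
#' @param d2 death probability on the tumor edge after detection (0.9).
#' @param R sanctuary radius in voxels; must not exceed
#'   \code{detection_radius}.
#' @param detection_radius radius in voxels at whose disc area the tumor is
#'   considered clinically detected (default 90, i.e. about 25,447 voxels).
#' @param max_voxels terminal population size in voxels (default 60,000).
#' @param growth_variant \code{"proliferative"} (cells die independently of
#'   their neighborhood) or \code{"quiescent"} (fully surrounded cells
#'   neither divide nor die).
#' @param selection_variant \code{"birth"} (drivers scale birth as
#'   \code{b*(1+s)^n}) or \code{"death"} (drivers reduce the regional death
#'   rate as \code{d*(1-s)^n}).
#' @param grid_half_width half-width of the square lattice; defaults to
#'   \code{ceiling(4*sqrt(max_voxels/pi))} so that a run reaching
#'   \code{max_voxels} stays far from the array boundary.
#'
#' @return An object of class \code{"sim_params"}.
#' @seealso [simulate_tumor()], [regime()]
#' @export
sim_params <- function(b = 0.7, s = 0.1, mu = 0.001,
                       d1 = 0.1, d2 = 0.9, R = 20,
                       detection_radius = 90, max_voxels = 60000,
                       growth_variant = c("proliferative", "quiescent"),
                       selection_variant = c("birth", "death"),
                       grid_half_width = NULL) {
  growth_variant <- match.arg(growth_variant)
  selection_variant <- match.arg(selection_variant)
  stopifnot(
    is.numeric(b), length(b) == 1, b >= 0, b <= 1,
    is.numeric(d1), length(d1) == 1, d1 >= 0, d1 <= 1,
    is.numeric(d2), length(d2) == 1, d2 >= 0, d2 <= 1,
    is.numeric(s), length(s) == 1, s >= 0,
    is.numeric(mu), length(mu) == 1, mu >= 0,
    is.numeric(R), length(R) == 1, R >= 0,
    is.numeric(detection_radius), detection_radius > 0,
    is.numeric(max_voxels), max_voxels >= 1
  )
  if (R > detection_radius)
    stop("sanctuary radius R must not exceed detection_radius")
  if (is.null(grid_half_width))
    grid_half_width <- ceiling(4 * sqrt(max_voxels / pi))
  p <- list(b = b, s = s, mu = mu, d1 = d1, d2 = d2, R = R,
            detection_radius = detection_radius, max_voxels = max_voxels,
            growth_variant = growth_variant,
            selection_variant = selection_variant,
            grid_half_width = as.integer(grid_half_width))
  class(p) <- "sim_params"
  p
}

#' Invasion regime implied by a parameter set
#'
#' @param params a [sim_params()] object.
#' @return \code{"driver-dependent"} if \code{d1 < b < d2},
#'   \code{"driver-independent"} if \code{d1 < d2 < b}, otherwise
#'   \code{"other"}.
#' @export
regime <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (params$d1 < params$b && params$b < params$d2) "driver-dependent"
  else if (params$d1 < params$d2 && params$d2 < params$b) "driver-independent"
  else "other"
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Lattice tumor simulation parameters\n")
  cat(sprintf("  b = %g, s = %g, mu = %g, d1 = %g, d2 = %g\n",
              x$b, x$s, x$mu, x$d1, x$d2))
  cat(sprintf("  sanctuary R = %g voxels, detection radius = %g voxels (%d voxels)\n",
              x$R, x$detection_radius, detection_threshold(x$detection_radius)))
  cat(sprintf("  terminal size = %g voxels, grid %d x %d\n",
              x$max_voxels, 2L * x$grid_half_width + 1L,
              2L * x$grid_half_width + 1L))
  cat(sprintf("  variants: %s growth, %s-rate selection; regime: %s\n",
              x$growth_variant, x$selection_variant, regime(x)))
  invisible(x)
}

#' Named scenario presets
#'
#' The four model quadrants (proliferative/quiescent crossed with
#' driver-dependent/driver-independent invasion) with the reference
#' parameter set mu = 0.001, s = 0.1, d1 = 0.1, b = 0.7 and d2 = 0.9
#' (driver-dependent) or 0.69 (driver-independent).
#'
#' @param name one of \code{"proliferative_driver_dependent"},
#'   \code{"proliferative_driver_independent"},
#'   \code{"quiescent_driver_dependent"},
#'   \code{"quiescent_driver_independent"}.
#' @param R sanctuary radius in voxels (reference values 20 or 60).
#' @param ... further arguments passed to [sim_params()] (e.g. scaled-down
#'   \code{detection_radius} and \code{max_voxels} for desk-scale runs).
#' @return A [sim_params()] object.
#' @export
scenario_preset <- function(name, R = 20, ...) {
  name <- match.arg(name, c("proliferative_driver_dependent",
                            "proliferative_driver_independent",
                            "quiescent_driver_dependent",
                            "quiescent_driver_independent"))
  growth <- if (startsWith(name, "quiescent")) "quiescent" else "proliferative"
  d2 <- if (endsWith(name, "dependent") && !endsWith(name, "independent")) 0.9 else 0.69
  sim_params(b = 0.7, s = 0.1, mu = 0.001, d1 = 0.1, d2 = d2, R = R,
             growth_variant = growth, ...)
}
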