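#' Haploid genome equivalents per mL of plasma
#'
#' @param plasma_conc cell-free DNA concentration in plasma (ng/mL).
#' @param genome_mass mass of one haploid genome (ng).
#' @return Integer HGE per mL (rounded).
#' @export
calibrate_hge <- function(plasma_conc, genome_mass) {
  if (plasma_conc <= 0 || genome_mass <= 0)
    stop("plasma concentration and genome mass must be positive")
  round(plasma_conc / genome_mass)
}

#' ctDNA decay rate from its blood half-life
#'
#' @param half_life_hours half-life of cell-free DNA in blood (hours);
#'   about 0.5 h, giving a per-day decay rate of 48 log(2) = 33.3.
#' @return Decay rate per day.
#' @export
decay_rate <- function(half_life_hours) {
  if (half_life_hours <= 0) stop("half-life must be positive")
  (24 / half_life_hours) * log(2)
}

#' Calibrated ctDNA shedding model constants
#'
#' Builds the full calibration chain for the fragment model. The steady-state
#' mean number of circulating tumor fragments is \code{C = N d q / eps + r}
#' for a tumor of \code{N} cells with mean death rate \code{d}, shedding
#' probability \code{q} per cell death and fragment decay rate \code{eps};
#' the growth term \code{r} is negligible against decay and fixed at 0.
#' \code{C} is anchored to plasma data: total HGE in plasma times the tumor
#' fraction observed at clinical detection
#' (\code{blood_volume * plasma_fraction * hge_per_ml * tumor_fraction}).
#' Solving \code{C = N d q / eps} at the detection-size tumor
#' (\code{n_cells_at_detection} cells, death rate \code{d_at_detection})
#' calibrates \code{q}. A blood draw of \code{draw_ml} scales all fragment
#' means by \code{draw_ml / blood_volume_ml}.
#'
#' The total-fragment constant used for \code{Ctot0} keeps its own rounded
#' HGE value (\code{ctot0_hge}, 8800 by default, versus the computed 8788
#' used in \code{C}); both are configurable.
#'
#' @param plasma_conc ng/mL (29).
#' @param genome_mass ng per haploid genome (0.0033).
#' @param blood_volume_ml total blood volume (5000).
#' @param plasma_fraction plasma fraction of blood (0.55).
#' @param tumor_fraction_at_detection tumor fraction of cfDNA at detection
#'   (0.01).
#' @param half_life_hours cfDNA half-life (0.5 h).
#' @param draw_ml blood draw volume (15 mL, i.e. 0.3\% of supply).
#' @param ctot0_hge HGE/mL constant used for the total fragment count (8800).
#' @param n_cells_at_detection 3D cell count at detection (3e9). For
#'   scaled-down simulations pass the 3D equivalent of the scaled detection
#'   size (see [voxels_to_3d_population()]) so the tumor fraction at
#'   detection stays at its calibrated value.
#' @param d_at_detection mean death rate at detection (0.1).
#' @return Object of class \code{"shedding_calibration"} with fields
#'   \code{hge_per_ml}, \code{C}, \code{epsilon}, \code{q},
#'   \code{draw_fraction}, \code{ctot0_mean}, \code{ch_mean}, \code{r} and
#'   the inputs.
#' @export
shedding_calibration <- function(plasma_conc = 29, genome_mass = 0.0033,
                                 blood_volume_ml = 5000,
                                 plasma_fraction = 0.55,
                                 tumor_fraction_at_detection = 0.01,
                                 half_life_hours = 0.5,
                                 draw_ml = 15,
                                 ctot0_hge = 8800,
                                 n_cells_at_detection = 3e9,
                                 d_at_detection = 0.1) {
  hge <- calibrate_hge(plasma_conc, genome_mass)
  eps <- decay_rate(half_life_hours)
  C <- blood_volume_ml * plasma_fraction * hge * tumor_fraction_at_detection
  q <- C * eps / (n_cells_at_detection * d_at_detection)
  draw_fraction <- draw_ml / blood_volume_ml
  ctot0_mean <- blood_volume_ml * plasma_fraction * ctot0_hge * draw_fraction
  cal <- list(plasma_conc = plasma_conc, genome_mass = genome_mass,
              blood_volume_ml = blood_volume_ml,
              plasma_fraction = plasma_fraction,
              tumor_fraction_at_detection = tumor_fraction_at_detection,
              half_life_hours = half_life_hours,
              draw_ml = draw_ml, ctot0_hge = ctot0_hge,
              n_cells_at_detection = n_cells_at_detection,
              d_at_detection = d_at_detection,
              hge_per_ml = hge, C = C, epsilon = eps, q = q, r = 0,
              draw_fraction = draw_fraction,
              ctot0_mean = ctot0_mean,
              ch_mean = 0.99 * ctot0_mean)
  class(cal) <- "shedding_calibration"
  cal
}

#' Shedding probability per cell death implied by a calibration
#'
#' @param cal a [shedding_calibration()] object.
#' @return Shedding probability \code{q} (full precision; about 0.027, the
#'   conventional rounded value being 0.026).
#' @export
calibrate_shedding_rate <- function(cal) {
  stopifnot(inherits(cal, "shedding_calibration"))
  cal$C * cal$epsilon / (cal$n_cells_at_detection * cal$d_at_detection)
}

#' @export
print.shedding_calibration <- function(x, ...) {
  cat("ctDNA shedding calibration\n")
  cat(sprintf("  HGE/mL plasma       : %d  (= %g ng/mL / %g ng)\n",
              x$hge_per_ml, x$plasma_conc, x$genome_mass))
  cat(sprintf("  tumor fragments C   : %s  (= %g mL x %g x %d x %g)\n",
              format(x$C, big.mark = ","), x$blood_volume_ml,
              x$plasma_fraction, x$hge_per_ml,
              x$tumor_fraction_at_detection))
  cat(sprintf("  decay rate epsilon  : %.4f / day  (half-life %g h)\n",
              x$epsilon, x$half_life_hours))
  cat(sprintf("  shedding prob. q    : %.2g  (full precision %.6f)\n",
              x$q, x$q))
  cat(sprintf("  draw fraction       : %.4f  (%g mL of %g mL)\n",
              x$draw_fraction, x$draw_ml, x$blood_volume_ml))
  cat(sprintf("  Ctot0 mean          : %s fragments/draw; Ch = %s\n",
              format(x$ctot0_mean, big.mark = ","),
              format(x$ch_mean, big.mark = ",")))
  invisible(x)
}

#' Mean tumor fragment count in a blood draw
#'
#' \code{Ct = N q d_bar / eps}, thinned by the draw fraction.
#'
#' @param N 3D tumor cell count (vectorized).
#' @param d_bar mean death rate of the whole tumor.
#' @param cal a [shedding_calibration()] object.
#' @return Mean fragment count for the draw.
#' @export
fragment_mean_total <- function(N, d_bar, cal) {
  stopifnot(all(N >= 0))
  N * cal$q * d_bar / cal$epsilon * cal$draw_fraction
}

#' Mean mutant fragment count in a blood draw
#'
#' \code{Cm = f_m N d_bar_m q / eps}, thinned by the draw fraction. The
#' spatially biased model uses the mutation's carrier mean death rate
#' \code{d_bar_m}; the unbiased (spatially uniform shedding) model
#' substitutes the tumor-wide mean \code{d_bar}.
#'
#' @param f_m tissue frequency of the mutation (vectorized).
#' @param N 3D tumor cell count.
#' @param d_bar_m carrier mean death rate (biased) or tumor mean (unbiased).
#' @param cal a [shedding_calibration()] object.
#' @return Mean mutant fragment count.
#' @export
mutation_fragment_mean <- function(f_m, N, d_bar_m, cal) {
  stopifnot(all(f_m >= 0), all(f_m <= 1), all(N >= 0))
  f_m * N * d_bar_m * cal$q / cal$epsilon * cal$draw_fraction
}

#' Sample a variant allele frequency from the fragment model
#'
#' Draws VAF = Pois(Cm/2) / Pois(Ct + Ch): the numerator is the count of
#' mutant fragments (diploid cells, one mutated copy, hence half the mutant
#' cell fragments), the denominator the total recovered fragments (tumor
#' plus healthy background), drawn independently. A denominator draw of 0
#' recovers no fragments and yields \code{NA} (undefined VAF, counted as
#' undetected downstream).
#'
#' @param cm_mean mean mutant fragment count (vectorized).
#' @param ct_mean mean total tumor fragment count.
#' @param ch_mean mean healthy fragment count.
#' @return Numeric vector of VAF draws in \[0, 1\] (or NA).
#' @export
sample_vaf <- function(cm_mean, ct_mean, ch_mean) {
  stopifnot(all(cm_mean >= 0), ct_mean >= 0, ch_mean >= 0)
  k <- length(cm_mean)
  num <- stats::rpois(k, cm_mean / 2)
  den <- stats::rpois(k, ct_mean + ch_mean)
  ifelse(den > 0, num / den, NA_real_)
}

#' Biased and unbiased VAF draws for a mutation table
#'
#' For one blood sample: computes biased/unbiased mutant fragment means for
#' every mutation, draws the shared healthy background once
#' (\code{Pois(Ch)}), and returns one VAF draw per mutation and model. The
#' per-mutation denominator is an independent \code{Pois(Ct)} tumor draw
#' plus the sample's healthy draw, so its marginal law is exactly
#' \code{Pois(Ct + Ch)}.
#'
#' @param mut_tab a [mutation_summary()] data frame.
#' @param m_voxels occupied voxel count of the lattice.
#' @param d_bar tumor-wide mean death rate.
#' @param cal a [shedding_calibration()] object.
#' @param sp a [scale_params()] object (voxel to 3D cell conversion).
#' @return \code{mut_tab} with columns \code{cm_biased_mean},
#'   \code{cm_unbiased_mean}, \code{vaf_biased}, \code{vaf_unbiased} added.
#' @export
sample_vaf_table <- function(mut_tab, m_voxels, d_bar, cal, sp) {
  N <- voxels_to_3d_population(m_voxels, sp)
  k <- nrow(mut_tab)
  mut_tab$cm_biased_mean <- mutation_fragment_mean(mut_tab$f_m, N,
                                                   mut_tab$d_bar_m, cal)
  mut_tab$cm_unbiased_mean <- mutation_fragment_mean(mut_tab$f_m, N,
                                                     d_bar, cal)
  ct <- fragment_mean_total(N, d_bar, cal)
  ch_draw <- stats::rpois(1, cal$ch_mean)
  den_b <- stats::rpois(k, ct) + ch_draw
  den_u <- stats::rpois(k, ct) + ch_draw
  num_b <- stats::rpois(k, mut_tab$cm_biased_mean / 2)
  num_u <- stats::rpois(k, mut_tab$cm_unbiased_mean / 2)
  mut_tab$vaf_biased <- ifelse(den_b > 0, num_b / den_b, NA_real_)
  mut_tab$vaf_unbiased <- ifelse(den_u > 0, num_u / den_u, NA_real_)
  mut_tab
}

#' Sampled VAF trajectory of a simulated tumor
#'
#' Walks the recorded trajectory of a [simulate_tumor()] run and, at every
#' recorded sweep, builds the per-mutation summary from the clone census and
#' draws biased and unbiased VAFs for one blood sample. Before the detection
#' sweep both regions shed at \code{d1}, so biased and unbiased models
#' coincide there.
#'
#' @param sim a \code{tumor_sim}.
#' @param cal a [shedding_calibration()] object.
#' @param sp a [scale_params()] object.
#' @return Data frame: \code{sweep}, \code{mutation_id}, \code{f_m},
#'   \code{d_bar_m}, \code{mean_distance}, \code{clonal},
#'   \code{cm_biased_mean}, \code{cm_unbiased_mean}, \code{vaf_biased},
#'   \code{vaf_unbiased}.
#' @export
vaf_trajectory <- function(sim, cal, sp = scale_params()) {
  stopifnot(inherits(sim, "tumor_sim"))
  tr <- sim$trajectory
  out <- lapply(split(tr, tr$sweep), function(snap) {
    d <- effective_death_rates(sim$params, snap$detected[1] > 0)
    mt <- mutation_summary(snap, sim$ledger, d[1], d[2])
    if (nrow(mt) == 0) return(NULL)
    m_vox <- sum(snap$core + snap$edge)
    d_bar <- mean_death_rate(snap, d[1], d[2])
    vt <- sample_vaf_table(mt, m_vox, d_bar, cal, sp)
    vt$sweep <- snap$sweep[1]
    vt
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(sweep = numeric(0), mutation_id = integer(0)))
  out <- out[order(out$sweep, out$mutation_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
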