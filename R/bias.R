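#' Inverse Simpson diversity of a set of clone fractions
#'
#' \code{D = 1 / sum(f_i^2)}: the effective number of clones, 1 for a
#' monoclonal population and k for k equally abundant clones.
#'
#' @param fractions non-negative fractions summing to 1.
#' @return Scalar diversity index, at least 1.
#' @export
inverse_simpson <- function(fractions) {
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be non-negative and sum to 1")
  1 / sum(fractions^2)
}

#' Blood-minus-tissue clone fraction differences
#'
#' Per-clone difference \code{delta_i = blood_i - tissue_i}, plus the mean
#' positive and mean negative difference over clones comprising at least
#' \code{min_tissue_fraction} of the tumor (default 10\%, the conventional
#' inclusion cutoff for these averages).
#'
#' @param blood,tissue named clone-fraction vectors over the same clone set
#'   (e.g. from [blood_clone_fractions()] and [tissue_clone_fractions()]).
#' @param min_tissue_fraction inclusion threshold for the averages.
#' @return List with \code{delta} (data frame: clone_id, tissue, blood,
#'   delta), \code{mean_positive}, \code{mean_negative} (NA when no clone
#'   qualifies).
#' @export
clone_fraction_differences <- function(blood, tissue,
                                       min_tissue_fraction = 0.10) {
  if (is.null(names(blood)) || is.null(names(tissue)) ||
      !setequal(names(blood), names(tissue)))
    stop("blood and tissue fractions must cover the same clones")
  blood <- blood[names(tissue)]
  delta <- blood - tissue
  keep <- tissue >= min_tissue_fraction
  pos <- delta[keep & delta > 0]
  neg <- delta[keep & delta < 0]
  list(
    delta = data.frame(clone_id = names(tissue),
                       tissue = as.numeric(tissue),
                       blood = as.numeric(blood),
                       delta = as.numeric(delta),
                       stringsAsFactors = FALSE),
    mean_positive = if (length(pos)) mean(pos) else NA_real_,
    mean_negative = if (length(neg)) mean(neg) else NA_real_
  )
}

#' Two-compartment expected clone fraction difference
#'
#' For a resident population of constant size \code{S} shedding at rate
#' \code{d1} and a single invasive subclone of size \code{x} shedding at
#' rate \code{d2}, the blood-minus-tissue fraction difference of the
#' invader is
#' \deqn{f(x) = \frac{d_2 x}{d_2 x + d_1 S} - \frac{x}{x + S}.}
#'
#' @param x invader size (vectorized, > 0).
#' @param S resident size (> 0).
#' @param d1,d2 core and edge death (shedding) rates (> 0).
#' @return The expected fraction difference.
#' @export
analytic_difference <- function(x, S, d1, d2) {
  stopifnot(all(x > 0), S > 0, d1 > 0, d2 > 0)
  d2 * x / (d2 * x + d1 * S) - x / (x + S)
}

#' Maximum of the two-compartment fraction difference
#'
#' Numerically maximizes [analytic_difference()] over the invader size
#' \code{x}. Since \code{f} depends on \code{x} only through \code{x/S},
#' the maximum value is independent of the resident size \code{S}. The
#' optimizer works on \code{log(x/S)} over a wide bracket, which makes the
#' search immune to the scale of \code{S}.
#'
#' @param S resident size.
#' @param d1,d2 core and edge shedding rates.
#' @return List with \code{x_star} (maximizing invader size) and
#'   \code{f_star} (maximum difference).
#' @export
max_clone_fraction_difference <- function(S, d1, d2) {
  stopifnot(S > 0, d1 > 0, d2 > 0)
  opt <- stats::optimize(function(u) analytic_difference(S * exp(u), S, d1, d2),
                         interval = c(-20, 20), maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  list(x_star = S * exp(opt$maximum), f_star = opt$objective)
}

#' Count driver mutations detectable at a VAF limit
#'
#' @param vaf numeric vector of sampled VAFs; \code{NA} (no fragments
#'   recovered) counts as undetected.
#' @param limit sequencing detection limit in (0, 1), e.g. 1e-3 or 1e-2.
#' @return Integer count of VAFs at or above the limit.
#' @export
count_detectable <- function(vaf, limit) {
  stopifnot(limit > 0, limit < 1)
  sum(!is.na(vaf) & vaf >= limit)
}

#' Percent change in detectable drivers due to spatial bias
#'
#' @param n_biased detectable driver count under spatially biased shedding.
#' @param n_unbiased detectable count under uniform shedding.
#' @return \code{100 * (n_biased - n_unbiased) / n_unbiased}; \code{NA} when
#'   \code{n_unbiased} is 0 (undefined, not an error).
#' @export
percent_spatial_bias <- function(n_biased, n_unbiased) {
  stopifnot(all(n_unbiased >= 0, na.rm = TRUE))
  ifelse(n_unbiased > 0, 100 * (n_biased - n_unbiased) / n_unbiased,
         NA_real_)
}

#' Normalize per-run time and bin a trajectory statistic
#'
#' Maps each run's time axis to \[0, 1\] (dividing by the run's final time),
#' averages the value within equal-width bins per run, then reports the
#' cross-run mean and sample standard deviation per bin.
#'
#' @param trajectory data frame with columns \code{run}, \code{time},
#'   \code{value}.
#' @param n_bins number of equal-width bins on \[0, 1\].
#' @return Data frame: \code{bin}, \code{mid} (bin midpoint), \code{mean},
#'   \code{sd}, \code{n_runs}.
#' @export
normalize_and_bin <- function(trajectory, n_bins = 20) {
  stopifnot(nrow(trajectory) > 0,
            all(c("run", "time", "value") %in% names(trajectory)))
  norm <- do.call(rbind, lapply(split(trajectory, trajectory$run), function(tr) {
    tmax <- max(tr$time)
    tr$t <- if (tmax > 0) tr$time / tmax else 0
    tr
  }))
  brk <- seq(0, 1, length.out = n_bins + 1)
  norm$bin <- pmin(pmax(findInterval(norm$t, brk, rightmost.closed = TRUE), 1L),
                   n_bins)
  per_run <- stats::aggregate(value ~ run + bin, data = norm, FUN = mean)
  agg_m <- stats::aggregate(value ~ bin, data = per_run, FUN = mean)
  agg_s <- stats::aggregate(value ~ bin, data = per_run,
                            FUN = function(v) if (length(v) > 1) stats::sd(v) else 0)
  agg_n <- stats::aggregate(value ~ bin, data = per_run, FUN = length)
  out <- data.frame(bin = agg_m$bin,
                    mid = (brk[agg_m$bin] + brk[agg_m$bin + 1]) / 2,
                    mean = agg_m$value, sd = agg_s$value,
                    n_runs = agg_n$value)
  out[order(out$bin), , drop = FALSE]
}

#' Fraction of driver mutations ever detectable along a run
#'
#' The share of all distinct driver mutations a run produced whose sampled
#' blood VAF reached the detection limit at any recorded sweep.
#'
#' @param vtraj a [vaf_trajectory()] data frame.
#' @param n_mutations_total total distinct driver mutations in the run's
#'   ledger (the denominator; includes mutations extinct before any sample).
#' @param limit VAF detection limit.
#' @param model \code{"biased"} (default) or \code{"unbiased"}.
#' @return Percentage in \[0, 100\].
#' @export
fraction_ever_detected <- function(vtraj, n_mutations_total, limit,
                                   model = c("biased", "unbiased")) {
  model <- match.arg(model)
  stopifnot(n_mutations_total >= 0)
  if (n_mutations_total == 0) return(NA_real_)
  v <- if (model == "biased") vtraj$vaf_biased else vtraj$vaf_unbiased
  hit <- !is.na(v) & v >= limit
  100 * length(unique(vtraj$mutation_id[hit])) / n_mutations_total
}
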