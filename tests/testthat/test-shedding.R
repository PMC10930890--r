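test_that("HGE per mL of plasma follows from concentration over genome mass", {
  expect_equal(calibrate_hge(29, 0.0033), 8788)
  expect_equal(calibrate_hge(0.0033, 0.0033), 1)
  expect_equal(calibrate_hge(58, 0.0033), 17576)  # linear in concentration
  expect_error(calibrate_hge(-1, 0.0033), "positive")
  expect_error(calibrate_hge(29, 0), "positive")
})

test_that("decay rate converts the blood half-life to a per-day rate", {
  expect_equal(decay_rate(0.5), 48 * log(2))
  expect_equal(decay_rate(0.5), 33.27, tolerance = 1e-3)
  expect_equal(decay_rate(24), log(2))
  expect_equal(decay_rate(1), 2 * decay_rate(2))  # doubling halves epsilon
  expect_error(decay_rate(0), "positive")
})

test_that("the calibration chain reproduces C, q and the draw fraction", {
  cal <- shedding_calibration()
  expect_equal(cal$hge_per_ml, 8788)
  expect_equal(cal$C, 5000 * 0.55 * 8788 * 0.01)
  expect_equal(cal$C, 241670)
  # full-precision q from the arithmetic oracle C * eps / (3e9 * 0.1)
  expect_equal(cal$q, 241670 * 48 * log(2) / 3e8)
  expect_equal(cal$q, 0.02680206, tolerance = 1e-7)
  expect_lt(abs(cal$q - 0.026), 0.002)  # conventional rounded value
  expect_equal(calibrate_shedding_rate(cal), cal$q)
  expect_equal(cal$draw_fraction, 0.003)
  expect_equal(cal$ctot0_mean, 5000 * 0.55 * 8800 * 0.003)
  expect_equal(cal$ch_mean, 0.99 * 72600)
  # doubling plasma concentration doubles q
  cal2 <- shedding_calibration(plasma_conc = 58)
  expect_equal(cal2$q / cal$q, calibrate_hge(58, 0.0033) / 8788)
})

test_that("calibration self-consistency: tumor fraction at detection recovers 1%", {
  cal <- shedding_calibration()
  ct <- fragment_mean_total(3e9, 0.1, cal)
  tf <- ct / cal$ctot0_mean
  # exact up to the 8788-vs-8800 rounding kept in Ctot0
  expect_equal(tf, 0.01 * 8788 / 8800, tolerance = 1e-12)
  expect_lt(abs(tf - 0.01), 2e-4)
})

test_that("blood fractions are death-rate-weighted and collapse to tissue when d1 = d2", {
  counts <- data.frame(clone_id = c(1L, 2L), core = c(100, 0),
                       edge = c(0, 100), sum_dist = 0)
  expect_equal(blood_clone_fractions(counts, 0.1, 0.9),
               c(`1` = 0.1, `2` = 0.9))
  expect_equal(tissue_clone_fractions(counts), c(`1` = 0.5, `2` = 0.5))
  # single clone across both regions: 1 regardless of rates
  one <- data.frame(clone_id = 4L, core = 30, edge = 70)
  expect_equal(unname(blood_clone_fractions(one, 0.1, 0.9)), 1)
  expect_error(blood_clone_fractions(counts, 0, 0), "zero death-weighted")
  empty <- data.frame(clone_id = integer(0), core = numeric(0),
                      edge = numeric(0))
  expect_error(blood_clone_fractions(empty, 0.1, 0.9), "empty")
})

test_that("blood equals tissue for d1 = d2 on 1000 random clone censuses", {
  set.seed(202)
  for (i in 1:1000) {
    k <- sample(1:8, 1)
    counts <- data.frame(clone_id = seq_len(k),
                         core = rpois(k, 30), edge = rpois(k, 30))
    counts <- counts[counts$core + counts$edge > 0, , drop = FALSE]
    if (nrow(counts) == 0) next
    d <- runif(1, 0.05, 0.95)
    expect_equal(blood_clone_fractions(counts, d, d),
                 tissue_clone_fractions(counts), tolerance = 1e-12)
    expect_equal(sum(blood_clone_fractions(counts, 0.1, 0.9)), 1,
                 tolerance = 1e-12)
  }
})

test_that("fragment means follow Ct = N q d/eps thinned by the draw", {
  cal <- shedding_calibration()
  ct <- fragment_mean_total(3e9, 0.1, cal)
  expect_equal(ct / cal$draw_fraction, 241670)  # whole-blood mean is C
  expect_equal(ct, 725.01, tolerance = 1e-5)
  expect_equal(fragment_mean_total(0, 0.1, cal), 0)
  expect_equal(fragment_mean_total(6e9, 0.1, cal), 2 * ct)  # linear in N
  expect_equal(fragment_mean_total(3e9, 0.2, cal), 2 * ct)  # linear in d
})

test_that("mutant fragment means use the carrier death rate; clonal mutations are model-invariant", {
  cal <- shedding_calibration()
  # f = 0.5 at detection: mean = 0.5 * C * draw_fraction
  cm <- mutation_fragment_mean(0.5, 3e9, 0.1, cal)
  expect_equal(cm, 0.5 * 241670 * 0.003)
  expect_equal(cm, 362.505, tolerance = 1e-6)
  expect_equal(mutation_fragment_mean(0, 3e9, 0.5, cal), 0)
  # clonal mutation: carrier mean death rate IS the tumor mean, so the
  # biased and unbiased fragment means coincide by construction
  counts <- data.frame(clone_id = 2L, core = 60, edge = 40, sum_dist = 0)
  led <- register_division(new_clone_ledger(), 1L, 3L)$ledger
  mt <- mutation_summary(counts, led, 0.1, 0.9)
  expect_true(mt$clonal)
  expect_equal(mutation_fragment_mean(mt$f_m, 3e9, mt$d_bar_m, cal),
               mutation_fragment_mean(mt$f_m, 3e9,
                                      mean_death_rate(counts, 0.1, 0.9), cal))
  expect_error(mutation_fragment_mean(1.5, 3e9, 0.1, cal))
})

test_that("VAF draws match the Poisson-ratio expectation", {
  cal <- shedding_calibration()
  cm <- mutation_fragment_mean(0.5, 3e9, 0.1, cal)
  ct <- fragment_mean_total(3e9, 0.1, cal)
  expected <- (cm / 2) / (ct + cal$ch_mean)
  expect_equal(expected, 0.0024966, tolerance = 1e-4)
  set.seed(303)
  draws <- sample_vaf(rep(cm, 1e5), ct, cal$ch_mean)
  expect_true(all(is.na(draws) | (draws >= 0 & draws <= 1)))
  se <- sd(draws, na.rm = TRUE) / sqrt(sum(!is.na(draws)))
  expect_lt(abs(mean(draws, na.rm = TRUE) - expected), 3 * se)
  # zero mutant mean gives VAF 0; zero denominator gives NA
  expect_equal(sample_vaf(0, ct, cal$ch_mean), 0)
  expect_true(is.na(sample_vaf(0, 0, 0)))
})

test_that("biased/unbiased VAF mean ratio approaches d_bar_m / d_bar under a dominant background", {
  cal <- shedding_calibration()
  f <- 0.3; N <- 3e9; dm <- 0.5; dbar <- 0.25
  bias <- mutation_fragment_mean(f, N, dm, cal) / 2
  unb <- mutation_fragment_mean(f, N, dbar, cal) / 2
  den <- fragment_mean_total(N, dbar, cal) + cal$ch_mean
  expect_equal((bias / den) / (unb / den), dm / dbar, tolerance = 1e-12)
})

test_that("sampled VAF tables flag pre-detection sweeps as bias-free", {
  st <- make_fixture(list(list(radius = 8, new_drivers = 1L),
                          list(radius = c(8, 12), new_drivers = 2L)),
                     grid_half_width = 16)
  counts <- region_counts(st, 6)
  cal <- shedding_calibration()
  mt <- mutation_summary(counts, st$ledger, 0.1, 0.1)  # pre-detection rates
  expect_equal(mt$d_bar_m, rep(0.1, nrow(mt)))
  set.seed(7)
  vt <- sample_vaf_table(mt, sum(counts$core + counts$edge),
                         mean_death_rate(counts, 0.1, 0.1), cal,
                         scale_params())
  expect_equal(vt$cm_biased_mean, vt$cm_unbiased_mean)
})
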