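test_that("Moore neighborhood has the right members, order and bounds behavior", {
  nb <- moore_neighbors(c(5, 5), c(20, 20))
  expect_equal(nrow(nb), 8)
  expect_setequal(paste(nb[, 1], nb[, 2]),
                  c("4 4", "4 5", "4 6", "5 4", "5 6", "6 4", "6 5", "6 6"))
  # fixed row-major offset order for reproducible tie-breaking
  expect_equal(nb[1, ], c(row = 4, col = 4))
  expect_equal(nb[8, ], c(row = 6, col = 6))
  expect_error(moore_neighbors(c(1, 1), c(20, 20)), "boundary")
  expect_error(moore_neighbors(c(0, 0), c(20, 20)), "boundary")
  for (p in list(c(2, 2), c(10, 3), c(19, 19)))
    expect_equal(nrow(moore_neighbors(p, c(20, 20))), 8)
})

test_that("division probability is b(1+s)^n clamped at 1", {
  expect_equal(birth_probability(0.7, 0.1, 0), 0.7)
  expect_equal(birth_probability(0.7, 0.1, 2), 0.7 * 1.21)
  expect_equal(birth_probability(0.7, 0.1, 4), 1.0)  # 1.0249 clamps
  expect_equal(birth_probability(0.7, 0.1, 0:4),
               pmin(1, 0.7 * 1.1^(0:4)))
})

test_that("regional death rate honors detection, sanctuary ties and the death-selection variant", {
  p <- sim_params(d1 = 0.1, d2 = 0.9, R = 20)
  expect_equal(death_rate(10, p, detected = TRUE), 0.1)
  expect_equal(death_rate(30, p, detected = TRUE), 0.9)
  expect_equal(death_rate(20, p, detected = TRUE), 0.1)  # tie -> core
  expect_equal(death_rate(30, p, detected = FALSE), 0.1) # pre-detection d1
  pd <- sim_params(d1 = 0.1, d2 = 0.9, R = 20, selection_variant = "death")
  expect_equal(death_rate(10, pd, detected = TRUE, n = 2), 0.1 * 0.9^2)
})

test_that("detection threshold is the disc area and matches the lattice count scale", {
  expect_equal(detection_threshold(90), 25447L)
  expect_equal(detection_threshold(90), as.integer(ceiling(pi * 90^2)))
  # integer-lattice disc count is within the rim band of the area threshold
  expect_lt(abs(lattice_disc_count(90) - detection_threshold(90)), 4 * 90)
  st <- make_fixture(list(list(radius = 4)), grid_half_width = 8,
                     detected = FALSE)
  expect_false(check_detection(st, sim_params(detection_radius = 90, R = 20)))
  st$detected <- TRUE
  expect_true(check_detection(st, sim_params(detection_radius = 90, R = 20)))
})

test_that("regime classification follows the d1/b/d2 ordering", {
  expect_equal(regime(sim_params(d1 = 0.1, b = 0.7, d2 = 0.9)), "driver-dependent")
  expect_equal(regime(sim_params(d1 = 0.1, b = 0.7, d2 = 0.69)), "driver-independent")
  expect_equal(regime(sim_params(d1 = 0.1, b = 0.1, d2 = 0.9)), "other")
  expect_error(sim_params(R = 100, detection_radius = 90), "detection_radius")
})

test_that("a chosen surrounded cell cannot divide; it dies only in the proliferative variant", {
  # 3x3 block: the center cell is fully surrounded
  regions <- list(list(radius = 1.5))
  for (variant in c("proliferative", "quiescent")) {
    p <- sim_params(b = 1, d1 = 1, d2 = 1, R = 3, detection_radius = 4,
                    max_voxels = 100, growth_variant = variant)
    center_events <- 0L
    for (seed in 1:120) {
      st <- make_fixture(regions, grid_half_width = 4, detected = TRUE)
      expect_equal(st$occupied, 9L)
      set.seed(seed)
      out <- tumor_step(st, p)
      ev <- out$events
      if (ev$row[1] == st$center[1] && ev$col[1] == st$center[2]) {
        center_events <- center_events + 1L
        expect_equal(ev$divided[1], 0L)  # no empty neighbor: cannot divide
        if (variant == "proliferative") {
          expect_equal(ev$died[1], 1L)   # d = 1: death independent of division
        } else {
          expect_equal(ev$died[1], 0L)   # quiescent: surrounded cells never die
        }
      } else {
        # border cells of the block always have empty neighbors: with b = 1
        # they divide, and with d = 1 they die in either variant
        expect_equal(ev$divided[1], 1L)
        expect_equal(ev$died[1], 1L)
      }
    }
    expect_gt(center_events, 0L)
  }
})

test_that("with certain birth and no death a division increments the population", {
  p <- sim_params(b = 1, d1 = 0, d2 = 0, R = 3, detection_radius = 4,
                  max_voxels = 100)
  st <- new_lattice_state(p)
  set.seed(1)
  out <- tumor_step(st, p)
  expect_equal(out$state$occupied, 2L)
  expect_equal(out$events$divided[1], 1L)
  expect_equal(out$events$died[1], 0L)
})

test_that("Poisson driver draws have the right rate and unique ids across a run", {
  # mu = 0: no clone beyond the founder can ever arise
  p0 <- sim_params(mu = 0, d1 = 0, d2 = 0, b = 1, R = 5, detection_radius = 6,
                   max_voxels = 300)
  s0 <- simulate_tumor(p0, seed = 3)
  expect_equal(length(s0$ledger$parent), 1L)
  # mutation count over many divisions approximates mu per division
  p1 <- sim_params(mu = 0.02, d1 = 0, d2 = 0, b = 1, R = 5,
                   detection_radius = 20, max_voxels = 1200)
  s1 <- simulate_tumor(p1, seed = 4)
  n_div <- s1$final_size - 1L  # no deaths: every division adds one voxel
  n_mut <- s1$state$next_mut_id - 1L
  se <- sqrt(p1$mu * n_div)
  expect_lt(abs(n_mut - p1$mu * n_div), 4 * se + 1)
  ids <- unlist(s1$ledger$newmuts)
  expect_equal(anyDuplicated(ids), 0L)  # infinite sites
})

test_that("terminal outcomes: no births goes extinct, no deaths grows to the cap", {
  pe <- sim_params(b = 0, d1 = 0.5, d2 = 0.5, R = 5, detection_radius = 6,
                   max_voxels = 100)
  se <- simulate_tumor(pe, seed = 5)
  expect_equal(se$status, "extinct")
  expect_equal(se$final_size, 0L)
  pg <- sim_params(b = 1, d1 = 0, d2 = 0, mu = 0.001, R = 5,
                   detection_radius = 10, max_voxels = 500)
  sg <- simulate_tumor(pg, seed = 6)
  expect_equal(sg$status, "max_voxels")
  expect_gte(sg$final_size, 500L)
  # monotone growth: population never decreases along the trajectory
  pop <- tapply(sg$trajectory$core + sg$trajectory$edge, sg$trajectory$sweep, sum)
  expect_true(all(diff(pop[order(as.numeric(names(pop)))]) >= 0))
})

test_that("identical seeds reproduce trajectories and ledgers bit for bit", {
  p <- sim_params(detection_radius = 12, max_voxels = 700, R = 6)
  a <- simulate_tumor(p, seed = 11, record_every = 5)
  b <- simulate_tumor(p, seed = 11, record_every = 5)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$ledger, b$ledger)
  expect_identical(a$state$grid, b$state$grid)
  c <- simulate_tumor(p, seed = 12, record_every = 5)
  expect_false(identical(a$state$grid, c$state$grid))
})

test_that("occupied-count bookkeeping matches a full grid scan after any event sequence", {
  p <- sim_params(detection_radius = 10, max_voxels = 400, R = 5,
                  d2 = 0.8)
  sim <- simulate_tumor(p, seed = 21, max_sweeps = 80)
  expect_equal(sim$final_size, sum(sim$state$grid > 0))
  expect_equal(sim$state$occupied, sum(sim$state$grid > 0))
  # every nonzero grid entry references a registered clone
  expect_true(all(sim$state$grid[sim$state$grid > 0] %in%
                  seq_along(sim$ledger$parent)))
})

test_that("with d1 = d2 the dynamics are invariant to the sanctuary radius", {
  base <- list(b = 0.7, d1 = 0.3, d2 = 0.3, mu = 0.01,
               detection_radius = 10, max_voxels = 350)
  a <- simulate_tumor(do.call(sim_params, c(base, R = 2)), seed = 31)
  b <- simulate_tumor(do.call(sim_params, c(base, R = 9)), seed = 31)
  # identical event streams: per-clone totals agree at every recorded sweep
  tot_a <- tapply(a$trajectory$core + a$trajectory$edge,
                  list(a$trajectory$sweep, a$trajectory$clone_id), sum)
  tot_b <- tapply(b$trajectory$core + b$trajectory$edge,
                  list(b$trajectory$sweep, b$trajectory$clone_id), sum)
  expect_identical(tot_a, tot_b)
  expect_identical(a$state$grid, b$state$grid)
})

test_that("quiescent tumors preserve a saturated interior", {
  p <- sim_params(b = 0.7, d1 = 0.6, d2 = 0.6, mu = 0, R = 5,
                  detection_radius = 10, max_voxels = 2000,
                  growth_variant = "quiescent")
  st <- make_fixture(list(list(radius = 8)), grid_half_width = 20,
                     detected = FALSE)
  set.seed(41)
  out <- tumor_step(st, p, n_events = 4000)
  g <- out$state$grid
  # cells well inside the initial disc were always fully surrounded:
  # they can never have been removed
  ctr <- st$center
  for (dr in -3:3) for (dc in -3:3)
    expect_gt(g[ctr[1] + dr, ctr[2] + dc], 0)
})
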