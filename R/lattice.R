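#' Moore neighborhood of a lattice coordinate
#'
#' Returns the eight surrounding coordinates of an interior lattice site in a
#' fixed row-major offset order (the same order used to enumerate candidate
#' daughter sites in the simulation engine, so tie-breaking is reproducible).
#'
#' @param pos integer vector \code{c(row, col)}, 1-based.
#' @param dim lattice dimensions \code{c(nrow, ncol)}.
#' @return An 8 x 2 integer matrix of \code{(row, col)} coordinates.
#' @export
moore_neighbors <- function(pos, dim) {
  stopifnot(length(pos) == 2, length(dim) == 2)
  if (pos[1] <= 1 || pos[1] >= dim[1] || pos[2] <= 1 || pos[2] >= dim[2])
    stop("position is on or outside the lattice boundary; grid too small")
  off <- cbind(c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
               c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  sweep_pos <- cbind(pos[1] + off[, 1], pos[2] + off[, 2])
  colnames(sweep_pos) <- c("row", "col")
  sweep_pos
}

#' Division probability of a cell with n driver mutations
#'
#' Under birth-rate selection a cell attempts division with probability
#' \code{b * (1 + s)^n}, clamped at 1 since it is used as a Bernoulli
#' parameter.
#'
#' @param b baseline birth probability.
#' @param s selective advantage per driver.
#' @param n driver mutation count (vectorized).
#' @return Division probability in \[0, 1\].
#' @export
birth_probability <- function(b, s, n) {
  stopifnot(all(n >= 0))
  pmin(1, b * (1 + s)^n)
}

#' Regional death probability of a cell
#'
#' Before detection every cell dies with the core rate \code{d1}. After
#' detection, cells within Euclidean distance \code{R} of the founder voxel
#' (ties included: distance exactly \code{R} is core) keep rate \code{d1}
#' while cells on the edge get \code{d2}. Under death-rate selection the
#' regional rate is further reduced multiplicatively per driver,
#' \code{d * (1 - s)^n}.
#'
#' @param distance Euclidean distance of the cell from the founder voxel
#'   (voxels); vectorized.
#' @param params a [sim_params()] object.
#' @param detected has the tumor reached the detection size?
#' @param n driver count of the cell (used only under
#'   \code{selection_variant = "death"}).
#' @return Death probability.
#' @export
death_rate <- function(distance, params, detected = TRUE, n = 0) {
  d <- ifelse(!detected | distance <= params$R + 1e-9, params$d1, params$d2)
  if (params$selection_variant == "death") d <- d * (1 - params$s)^n
  d
}

#' Voxel count at which a tumor is considered detected
#'
#' Detection is triggered by population size rather than a geometric radius
#' estimate: the tumor is detected once it occupies at least the area of a
#' disc of the detection radius, \code{ceiling(pi * r^2)} voxels. Robust to
#' ragged growth fronts.
#'
#' @param detection_radius radius in voxels.
#' @return Integer voxel threshold.
#' @export
detection_threshold <- function(detection_radius) {
  as.integer(ceiling(pi * detection_radius^2))
}

#' Has a lattice state reached the detection size?
#'
#' Detection latches: once a state is flagged detected it stays detected even
#' if the population later shrinks below the threshold.
#'
#' @param state a \code{lattice_state}.
#' @param params a [sim_params()] object.
#' @return Logical.
#' @export
check_detection <- function(state, params) {
  isTRUE(state$detected) ||
    state$occupied >= detection_threshold(params$detection_radius)
}

# ---- clone ledger ----------------------------------------------------------

#' Create a clone ledger with a founder clone
#'
#' The ledger records the clone genealogy: parent pointers, per-clone counts
#' of driver mutations, the event index at which each clone arose, and the
#' driver mutation ids newly acquired at that division (a clone's full driver
#' set is the union along its ancestry). Clone identity equals driver
#' genotype: a division acquiring no new driver does not create a clone.
#'
#' @param founder_drivers integer vector of driver ids carried by the founder
#'   (usually empty).
#' @return An object of class \code{"clone_ledger"}.
#' @export
new_clone_ledger <- function(founder_drivers = integer(0)) {
  led <- list(parent = 0L,
              ndrv = length(founder_drivers),
              birth_event = 0,
              newmuts = list(as.integer(founder_drivers)))
  class(led) <- "clone_ledger"
  led
}

#' Register a division in the clone ledger
#'
#' Returns the parent clone id unchanged when no new driver was acquired;
#' otherwise creates a child clone whose driver set is the parent's set plus
#' the new ids. Reusing a mutation id violates the infinite-sites assumption
#' and is an error.
#'
#' @param ledger a [new_clone_ledger()] object.
#' @param parent_id id of the dividing cell's clone.
#' @param new_driver_ids integer vector of newly acquired driver ids
#'   (possibly empty).
#' @param birth_event event index of the division (bookkeeping only).
#' @return List with elements \code{ledger} (updated) and \code{clone_id}.
#' @export
register_division <- function(ledger, parent_id, new_driver_ids = integer(0),
                              birth_event = NA_real_) {
  stopifnot(inherits(ledger, "clone_ledger"))
  if (parent_id < 1 || parent_id > length(ledger$parent))
    stop("parent clone ", parent_id, " does not exist")
  new_driver_ids <- as.integer(new_driver_ids)
  if (length(new_driver_ids) == 0)
    return(list(ledger = ledger, clone_id = parent_id))
  used <- unlist(ledger$newmuts, use.names = FALSE)
  if (any(new_driver_ids %in% used) || anyDuplicated(new_driver_ids))
    stop("mutation id already assigned: infinite-sites violation")
  ledger$parent <- c(ledger$parent, as.integer(parent_id))
  ledger$ndrv <- c(ledger$ndrv, ledger$ndrv[parent_id] + length(new_driver_ids))
  ledger$birth_event <- c(ledger$birth_event, birth_event)
  ledger$newmuts <- c(ledger$newmuts, list(new_driver_ids))
  list(ledger = ledger, clone_id = length(ledger$parent))
}

#' Full driver set of a clone
#'
#' @param ledger a clone ledger.
#' @param clone_id clone id.
#' @return Integer vector of driver mutation ids (union along ancestry).
#' @export
clone_drivers <- function(ledger, clone_id) {
  ids <- integer(0)
  k <- clone_id
  while (k != 0L) {
    ids <- c(ledger$newmuts[[k]], ids)
    k <- ledger$parent[k]
  }
  ids
}

#' @export
as.data.frame.clone_ledger <- function(x, ...) {
  data.frame(
    clone_id = seq_along(x$parent),
    parent_id = x$parent,
    n = x$ndrv,
    birth_event = x$birth_event,
    driver_ids = vapply(seq_along(x$parent), function(i)
      paste(clone_drivers(x, i), collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
}

#' @export
print.clone_ledger <- function(x, ...) {
  cat("Clone ledger:", length(x$parent), "clones,",
      length(unlist(x$newmuts)), "driver mutations\n")
  invisible(x)
}

# ---- lattice state ---------------------------------------------------------

#' Construct a lattice state with a single founder cell
#'
#' @param params a [sim_params()] object; sets the grid size.
#' @return An object of class \code{"lattice_state"}: the occupancy grid
#'   (0 = empty, otherwise clone id), the fixed founder-centered coordinate
#'   system, the clone ledger, and the event/sweep clocks.
#' @export
new_lattice_state <- function(params) {
  L <- 2L * params$grid_half_width + 1L
  grid <- matrix(0L, L, L)
  ctr <- c(params$grid_half_width + 1L, params$grid_half_width + 1L)
  grid[ctr[1], ctr[2]] <- 1L
  state <- list(grid = grid, center = ctr, detected = FALSE,
                event_index = 0, sweep = 0, sweep_quota = 1,
                occupied = 1L,
                ledger = new_clone_ledger(),
                next_mut_id = 1L)
  class(state) <- "lattice_state"
  state
}

#' @export
print.lattice_state <- function(x, ...) {
  cat(sprintf("Lattice state: %d occupied voxels, %d clones, sweep %g, %s\n",
              x$occupied, length(x$ledger$parent), x$sweep,
              if (x$detected) "detected" else "pre-detection"))
  invisible(x)
}

.engine_call <- function(state, params, max_events, max_sweeps,
                         record_every, record_events) {
  cpp_run_engine(state$grid, as.integer(state$center),
                 state$detected, state$event_index, state$sweep,
                 state$sweep_quota,
                 as.integer(state$ledger$parent),
                 as.integer(state$ledger$ndrv),
                 as.numeric(state$ledger$birth_event),
                 state$ledger$newmuts,
                 as.integer(state$next_mut_id),
                 unclass(params),
                 max_events, max_sweeps,
                 as.integer(record_every), record_events)
}

.state_from_engine <- function(res, state) {
  led <- res$ledger
  class(led) <- "clone_ledger"
  out <- list(grid = res$grid, center = state$center,
              detected = res$detected,
              event_index = res$event_index, sweep = res$sweep,
              sweep_quota = res$sweep_quota,
              occupied = as.integer(res$occupied),
              ledger = led, next_mut_id = res$next_mut_id)
  class(out) <- "lattice_state"
  out
}

#' Advance a lattice state by single events
#'
#' Runs the per-event update: choose an occupied voxel uniformly at random;
#' it attempts division with probability [birth_probability()] into a
#' uniformly chosen empty Moore neighbor (a division draws a Poisson(mu)
#' number of new driver mutations, founding a new clone if positive); then
#' the same chosen cell dies with its regional death rate ([death_rate()]).
#' In the quiescent growth variant a fully surrounded cell neither divides
#' nor dies. Uses R's global RNG stream; seed with [set.seed()].
#'
#' @param state a \code{lattice_state}.
#' @param params a [sim_params()] object.
#' @param n_events number of events to run (default 1).
#' @return List with the advanced \code{state}, the engine \code{status}
#'   (\code{"max_events"}, \code{"extinct"}, \code{"max_voxels"} or
#'   \code{"boundary"}), and \code{events}, a data frame with one row per
#'   event (chosen cell, division, daughter placement, mutations, death).
#' @export
tumor_step <- function(state, params, n_events = 1) {
  stopifnot(inherits(state, "lattice_state"), inherits(params, "sim_params"))
  if (state$occupied < 1) stop("empty lattice: no cell to choose")
  res <- .engine_call(state, params, max_events = n_events,
                      max_sweeps = Inf, record_every = 0L,
                      record_events = TRUE)
  list(state = .state_from_engine(res, state), status = res$status,
       events = res$events)
}

#' Simulate a tumor from a single founder cell
#'
#' Runs the boundary-driven growth model from one cell until the population
#' either goes extinct or reaches \code{params$max_voxels} (or a sweep cap,
#' if given). Time is measured in sweeps: one sweep equals as many
#' cell-choice events as there are occupied voxels when the sweep starts.
#' The trajectory records, every \code{record_every} sweeps, the census of
#' every live clone split into core (distance from founder at most \code{R})
#' and edge voxels, together with the clone's summed distance from the
#' founder — everything downstream shedding and bias metrics need.
#'
#' @param params a [sim_params()] object.
#' @param seed integer seed for R's RNG; identical seeds give bit-identical
#'   trajectories. \code{NULL} continues the current RNG stream.
#' @param record_every trajectory cadence in sweeps (default 10).
#' @param max_sweeps optional sweep cap (default unlimited); a run stopped by
#'   the cap has status \code{"max_sweeps"}.
#' @return An object of class \code{"tumor_sim"} with elements
#'   \code{trajectory} (data frame: sweep, clone_id, core, edge, sum_dist,
#'   detected), \code{ledger}, \code{state} (final \code{lattice_state}),
#'   \code{status}, \code{detected}, \code{detection_sweep},
#'   \code{final_size}, \code{sweeps}, \code{params}, \code{seed}.
#' @examples
#' p <- sim_params(detection_radius = 12, max_voxels = 600, R = 6)
#' sim <- simulate_tumor(p, seed = 1, record_every = 5)
#' summary(sim)
#' @export
simulate_tumor <- function(params, seed = NULL, record_every = 10,
                           max_sweeps = Inf) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  state <- new_lattice_state(params)
  res <- .engine_call(state, params, max_events = Inf,
                      max_sweeps = max_sweeps,
                      record_every = record_every, record_events = FALSE)
  if (res$status == "boundary")
    stop("tumor reached the lattice boundary at ", res$occupied,
         " voxels; enlarge grid_half_width")
  led <- res$ledger
  class(led) <- "clone_ledger"
  out <- list(
    params = params, seed = seed, record_every = record_every,
    trajectory = res$snapshots,
    ledger = led,
    state = .state_from_engine(res, state),
    status = res$status,
    detected = res$detected,
    detection_event = res$detection_event,
    detection_sweep = res$detection_sweep,
    final_size = as.integer(res$occupied),
    sweeps = res$sweep,
    events = res$event_index
  )
  class(out) <- "tumor_sim"
  out
}

#' @export
print.tumor_sim <- function(x, ...) {
  cat("Boundary-driven lattice tumor simulation\n")
  cat(sprintf("  regime: %s (%s growth, %s-rate selection)\n",
              regime(x$params), x$params$growth_variant,
              x$params$selection_variant))
  cat(sprintf("  terminated: %s after %g sweeps (%.3g events); final size %d voxels\n",
              x$status, x$sweeps, x$events, x$final_size))
  if (x$detected)
    cat(sprintf("  detected at sweep %g (threshold %d voxels)\n",
                x$detection_sweep,
                detection_threshold(x$params$detection_radius)))
  cat(sprintf("  clones: %d total, %d alive; driver mutations: %d\n",
              length(x$ledger$parent),
              length(unique(x$trajectory$clone_id[
                x$trajectory$sweep == max(x$trajectory$sweep)])),
              x$state$next_mut_id - 1L))
  invisible(x)
}

#' @export
summary.tumor_sim <- function(object, ...) {
  tr <- object$trajectory
  last <- tr[tr$sweep == max(tr$sweep), , drop = FALSE]
  counts <- region_counts(object$state, object$params$R)
  tis <- tissue_clone_fractions(counts)
  d <- effective_death_rates(object$params, object$detected)
  blo <- blood_clone_fractions(counts, d[1], d[2])
  out <- list(
    regime = regime(object$params),
    status = object$status,
    final_size = object$final_size,
    sweeps = object$sweeps,
    detected = object$detected,
    detection_sweep = object$detection_sweep,
    n_clones_total = length(object$ledger$parent),
    n_clones_alive = nrow(last),
    n_mutations = object$state$next_mut_id - 1L,
    max_driver_count = max(object$ledger$ndrv),
    inverse_simpson_tissue = inverse_simpson(tis),
    inverse_simpson_blood = inverse_simpson(blo)
  )
  class(out) <- "summary.tumor_sim"
  out
}

#' @export
print.summary.tumor_sim <- function(x, ...) {
  cat(sprintf("%s run: %s at %d voxels after %g sweeps\n",
              x$regime, x$status, x$final_size, x$sweeps))
  cat(sprintf("  clones: %d total, %d alive; %d driver mutations (max per clone %d)\n",
              x$n_clones_total, x$n_clones_alive, x$n_mutations,
              x$max_driver_count))
  cat(sprintf("  inverse Simpson diversity: tissue %.3f, blood %.3f\n",
              x$inverse_simpson_tissue, x$inverse_simpson_blood))
  invisible(x)
}

#' Plot the final lattice of a simulated tumor
#'
#' Draws the occupancy grid cropped to the tumor's bounding box, coloring
#' voxels by clone id, with the sanctuary radius overlaid.
#'
#' @param x a \code{tumor_sim}.
#' @param ... passed to [graphics::image()].
#' @export
plot.tumor_sim <- function(x, ...) {
  g <- x$state$grid
  occ <- which(g > 0, arr.ind = TRUE)
  rr <- range(occ[, 1]); cc <- range(occ[, 2])
  sub <- g[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  ids <- sort(unique(as.vector(sub)))
  ids <- ids[ids > 0]
  z <- matrix(match(sub, ids), nrow(sub), ncol(sub))
  cols <- grDevices::hcl.colors(max(length(ids), 2L), "Spectral")
  graphics::image(seq_len(nrow(sub)) + rr[1] - 1L,
                  seq_len(ncol(sub)) + cc[1] - 1L,
                  z, col = cols, asp = 1,
                  xlab = "row", ylab = "col",
                  main = sprintf("%s, %d voxels", regime(x$params),
                                 x$final_size), ...)
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(x$state$center[1] + x$params$R * cos(th),
                  x$state$center[2] + x$params$R * sin(th), lwd = 2)
  invisible(x)
}

#' Core/edge death rates in effect for a detection status
#'
#' @param params a [sim_params()] object.
#' @param detected logical; before detection both regions share \code{d1}.
#' @return Numeric vector \code{c(core, edge)}.
#' @export
effective_death_rates <- function(params, detected = TRUE) {
  if (detected) c(core = params$d1, edge = params$d2)
  else c(core = params$d1, edge = params$d1)
}
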