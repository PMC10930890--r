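#' Build a deterministic lattice state from discs and annuli
#'
#' Constructs a small, hand-checkable tumor for testing the shedding and
#' bias stages without running a simulation. Each region is a disc or
#' annulus of voxels (by Euclidean distance of voxel centers from the
#' lattice center) assigned to one clone; clones are chained through the
#' ledger via [register_division()], so driver sets nest along the given
#' parentage. Overlapping regions are an error.
#'
#' @param regions list of region specs. Each spec is a list with fields:
#'   \describe{
#'     \item{radius}{disc radius, or \code{c(inner, outer)} for an annulus
#'       covering distances in (inner, outer\];}
#'     \item{new_drivers}{integer ids of drivers acquired by this region's
#'       clone relative to its parent (empty = same clone as parent);}
#'     \item{parent}{index of the parent region (default: the previous
#'       region; the first region descends from the founder clone).}
#'   }
#' @param grid_half_width half-width of the square lattice.
#' @param detected logical flag to stamp on the state (default TRUE so the
#'   core/edge death split applies downstream).
#' @return A \code{lattice_state} whose ledger and occupancy are consistent.
#' @examples
#' st <- make_fixture(list(
#'   list(radius = 20),
#'   list(radius = c(20, 25), new_drivers = c(1L, 2L))
#' ), grid_half_width = 30)
#' @export
make_fixture <- function(regions, grid_half_width = 40, detected = TRUE) {
  if (length(regions) == 0) stop("empty fixture spec: no regions")
  L <- 2L * grid_half_width + 1L
  ctr <- c(grid_half_width + 1L, grid_half_width + 1L)
  dist <- sqrt(outer((seq_len(L) - ctr[1])^2, (seq_len(L) - ctr[2])^2, "+"))
  grid <- matrix(0L, L, L)
  ledger <- new_clone_ledger()
  region_clone <- integer(length(regions))
  for (i in seq_along(regions)) {
    rg <- regions[[i]]
    if (is.null(rg$radius)) stop("region ", i, " has no radius")
    rad <- rg$radius
    mask <- if (length(rad) == 1) dist <= rad + 1e-9
            else dist > rad[1] + 1e-9 & dist <= rad[2] + 1e-9
    if (!any(mask)) stop("region ", i, " covers no voxels")
    if (any(grid[mask] != 0)) stop("region ", i, " overlaps a previous region")
    parent_region <- if (!is.null(rg$parent)) rg$parent else i - 1L
    parent_clone <- if (parent_region == 0L) 1L else region_clone[parent_region]
    reg <- register_division(ledger, parent_clone,
                             as.integer(rg$new_drivers %||% integer(0)))
    ledger <- reg$ledger
    region_clone[i] <- reg$clone_id
    grid[mask] <- reg$clone_id
  }
  state <- list(grid = grid, center = ctr, detected = detected,
                event_index = 0, sweep = 0, sweep_quota = sum(grid > 0),
                occupied = sum(grid > 0),
                ledger = ledger, next_mut_id = max(c(0L,
                  unlist(ledger$newmuts, use.names = FALSE))) + 1L)
  class(state) <- "lattice_state"
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of lattice voxels within a disc
#'
#' Brute-force enumeration of voxel centers within Euclidean distance r of
#' the center voxel; the integer-lattice counterpart of the disc area
#' \code{pi r^2}.
#'
#' @param r radius in voxels.
#' @return Integer voxel count.
#' @export
lattice_disc_count <- function(r) {
  k <- ceiling(r)
  sum(outer((-k:k)^2, (-k:k)^2, "+") <= r^2 + 1e-9)
}
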