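#' Per-clone census of a lattice state split by region
#'
#' Exact count of every live clone's voxels inside (core) and outside (edge)
#' the sanctuary disc of radius \code{R} around the founder voxel, plus the
#' clone's summed Euclidean distance from the founder. Voxels at distance
#' exactly \code{R} belong to the core.
#'
#' @param state a \code{lattice_state} (or the \code{state} element of a
#'   \code{tumor_sim}).
#' @param R sanctuary radius in voxels.
#' @return Data frame with columns \code{clone_id}, \code{core}, \code{edge},
#'   \code{sum_dist}, one row per live clone.
#' @export
region_counts <- function(state, R) {
  g <- state$grid
  occ <- which(g > 0)
  if (length(occ) == 0)
    return(data.frame(clone_id = integer(0), core = numeric(0),
                      edge = numeric(0), sum_dist = numeric(0)))
  nr <- nrow(g)
  rows <- (occ - 1L) %% nr + 1L
  cols <- (occ - 1L) %/% nr + 1L
  dist <- sqrt((rows - state$center[1])^2 + (cols - state$center[2])^2)
  id <- g[occ]
  core <- dist <= R + 1e-9
  out <- data.frame(
    clone_id = sort(unique(id)),
    core = as.numeric(rowsum(as.numeric(core), id)[, 1]),
    edge = as.numeric(rowsum(as.numeric(!core), id)[, 1]),
    sum_dist = as.numeric(rowsum(dist, id)[, 1])
  )
  rownames(out) <- NULL
  out
}

.check_counts <- function(counts) {
  stopifnot(is.data.frame(counts),
            all(c("clone_id", "core", "edge") %in% names(counts)))
  if (any(counts$core < 0) || any(counts$edge < 0))
    stop("negative region counts")
}

#' Clone fractions in the tumor tissue
#'
#' @param counts a [region_counts()] data frame.
#' @return Named numeric vector of clone fractions summing to 1.
#' @export
tissue_clone_fractions <- function(counts) {
  .check_counts(counts)
  tot <- counts$core + counts$edge
  if (sum(tot) <= 0) stop("empty tumor: no occupied voxels")
  structure(tot / sum(tot), names = as.character(counts$clone_id))
}

#' Clone fractions in the ctDNA population
#'
#' Shedding is proportional to the regional death rate, so the blood
#' fraction of clone i is the death-rate-weighted average
#' \deqn{\sum_j d_j N_{ij} / \sum_i \sum_j d_j N_{ij}}
#' over regions j in \{core, edge\}. With \code{d_core == d_edge} this
#' reduces exactly to [tissue_clone_fractions()].
#'
#' @param counts a [region_counts()] data frame.
#' @param d_core,d_edge regional death rates in effect (see
#'   [effective_death_rates()]).
#' @return Named numeric vector of blood clone fractions summing to 1.
#' @export
blood_clone_fractions <- function(counts, d_core, d_edge) {
  .check_counts(counts)
  if (sum(counts$core + counts$edge) <= 0) stop("empty tumor: no occupied voxels")
  w <- d_core * counts$core + d_edge * counts$edge
  if (sum(w) <= 0)
    stop("zero death-weighted mass: no shedding cells (all weights zero)")
  structure(w / sum(w), names = as.character(counts$clone_id))
}

#' Per-mutation summary table
#'
#' For every driver mutation with at least one live carrier, computes the
#' tissue frequency \code{f_m} (carriers / occupied voxels), the carrier
#' mean death rate \code{d_bar_m} (carrier-weighted mean of the regional
#' rates), the mean carrier distance from the founder voxel, and whether the
#' mutation is clonal (\code{f_m == 1}). Carriers are aggregated over the
#' genealogy: every cell of the clone in which the mutation arose and of all
#' its descendant clones carries it.
#'
#' @param counts a [region_counts()] data frame (or a trajectory snapshot
#'   with the same columns).
#' @param ledger the run's \code{clone_ledger}.
#' @param d_core,d_edge regional death rates in effect.
#' @param include_extinct if TRUE, also report mutations with zero live
#'   carriers (\code{f_m = 0}, rates NA).
#' @return Data frame: \code{mutation_id}, \code{origin_clone}, \code{f_m},
#'   \code{d_bar_m}, \code{mean_distance}, \code{clonal}.
#' @export
mutation_summary <- function(counts, ledger, d_core, d_edge,
                             include_extinct = FALSE) {
  .check_counts(counts)
  nclones <- length(ledger$parent)
  core <- edge <- sdist <- numeric(nclones)
  core[counts$clone_id] <- counts$core
  edge[counts$clone_id] <- counts$edge
  if (!is.null(counts$sum_dist)) sdist[counts$clone_id] <- counts$sum_dist
  # subtree totals: children have larger ids than parents, accumulate upward
  for (k in rev(seq_len(nclones))) {
    p <- ledger$parent[k]
    if (p > 0L) {
      core[p] <- core[p] + core[k]
      edge[p] <- edge[p] + edge[k]
      sdist[p] <- sdist[p] + sdist[k]
    }
  }
  m_total <- sum(counts$core + counts$edge)
  origin <- rep.int(seq_len(nclones),
                    vapply(ledger$newmuts, length, integer(1)))
  mut_id <- unlist(ledger$newmuts, use.names = FALSE)
  if (length(mut_id) == 0)
    return(data.frame(mutation_id = integer(0), origin_clone = integer(0),
                      f_m = numeric(0), d_bar_m = numeric(0),
                      mean_distance = numeric(0), clonal = logical(0)))
  carriers <- core[origin] + edge[origin]
  out <- data.frame(
    mutation_id = mut_id,
    origin_clone = origin,
    f_m = carriers / m_total,
    d_bar_m = ifelse(carriers > 0,
                     (d_core * core[origin] + d_edge * edge[origin]) / carriers,
                     NA_real_),
    mean_distance = ifelse(carriers > 0, sdist[origin] / carriers, NA_real_),
    clonal = carriers == m_total
  )
  out <- out[order(out$mutation_id), , drop = FALSE]
  rownames(out) <- NULL
  if (!include_extinct) out <- out[carriers[order(mut_id)] > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tumor-wide mean death rate from a region census
#'
#' @param counts a [region_counts()] data frame.
#' @param d_core,d_edge regional death rates in effect.
#' @return Scalar mean death rate.
#' @export
mean_death_rate <- function(counts, d_core, d_edge) {
  .check_counts(counts)
  tot <- sum(counts$core + counts$edge)
  if (tot <= 0) stop("empty tumor")
  (d_core * sum(counts$core) + d_edge * sum(counts$edge)) / tot
}
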