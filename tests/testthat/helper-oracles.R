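# Independent oracles used across tests: brute-force per-cell enumeration of
# region counts and mutation carriers, straight from the grid, with no reuse
# of the package's census code paths.

oracle_region_counts <- function(state, R) {
  g <- state$grid
  occ <- which(g > 0, arr.ind = TRUE)
  out <- list()
  for (k in seq_len(nrow(occ))) {
    id <- g[occ[k, 1], occ[k, 2]]
    d <- sqrt((occ[k, 1] - state$center[1])^2 + (occ[k, 2] - state$center[2])^2)
    key <- as.character(id)
    if (is.null(out[[key]])) out[[key]] <- c(core = 0, edge = 0, sum_dist = 0)
    if (d <= R + 1e-9) out[[key]]["core"] <- out[[key]]["core"] + 1
    else out[[key]]["edge"] <- out[[key]]["edge"] + 1
    out[[key]]["sum_dist"] <- out[[key]]["sum_dist"] + d
  }
  ids <- sort(as.integer(names(out)))
  data.frame(clone_id = ids,
             core = sapply(as.character(ids), function(k) out[[k]]["core"]),
             edge = sapply(as.character(ids), function(k) out[[k]]["edge"]),
             sum_dist = sapply(as.character(ids), function(k) out[[k]]["sum_dist"]),
             row.names = NULL)
}

# per-cell mutation carrier enumeration via each clone's full driver set
oracle_mutation_summary <- function(state, R, d_core, d_edge) {
  g <- state$grid
  led <- state$ledger
  occ <- which(g > 0, arr.ind = TRUE)
  m_total <- nrow(occ)
  drv <- lapply(seq_along(led$parent), function(i)
    latticeshed::clone_drivers(led, i))
  muts <- sort(unique(unlist(drv)))
  rows <- lapply(muts, function(m) {
    carries <- vapply(drv, function(v) m %in% v, logical(1))
    cnt <- 0; dsum <- 0; core_n <- 0; edge_n <- 0
    for (k in seq_len(m_total)) {
      id <- g[occ[k, 1], occ[k, 2]]
      if (carries[id]) {
        d <- sqrt((occ[k, 1] - state$center[1])^2 +
                  (occ[k, 2] - state$center[2])^2)
        cnt <- cnt + 1; dsum <- dsum + d
        if (d <= R + 1e-9) core_n <- core_n + 1 else edge_n <- edge_n + 1
      }
    }
    if (cnt == 0) return(NULL)
    data.frame(mutation_id = m, f_m = cnt / m_total,
               d_bar_m = (d_core * core_n + d_edge * edge_n) / cnt,
               mean_distance = dsum / cnt, clonal = cnt == m_total)
  })
  do.call(rbind, rows)
}

# random multi-annulus fixture for property tests
random_fixture <- function(n_regions = 3, half_width = 18) {
  radii <- sort(sample(3:(half_width - 2), n_regions))
  regions <- list(list(radius = radii[1]))
  nid <- 1L
  if (n_regions > 1) for (i in 2:n_regions) {
    k <- sample(0:2, 1)
    drv <- if (k > 0) seq.int(nid, nid + k - 1L) else integer(0)
    nid <- nid + k
    regions[[i]] <- list(radius = c(radii[i - 1], radii[i]), new_drivers = drv)
  }
  make_fixture(regions, grid_half_width = half_width)
}
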