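#' Read a flat key/value run configuration
#'
#' Parses a plain-text configuration of \code{key = value} lines (\code{#}
#' starts a comment). Keys must be [sim_params()] argument names; values are
#' coerced to the argument's natural type.
#'
#' @param path file path.
#' @return A [sim_params()] object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, integer(1)) != 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, `[`, character(1), 2)
  allowed <- names(formals(sim_params))
  unknown <- setdiff(keys, allowed)
  if (length(unknown)) stop("unknown config key: ", paste(unknown, collapse = ", "))
  args <- lapply(seq_along(keys), function(i) {
    if (keys[i] %in% c("growth_variant", "selection_variant")) vals[i]
    else as.numeric(vals[i])
  })
  names(args) <- keys
  do.call(sim_params, args)
}

#' Write the outputs of a simulated run
#'
#' Writes the run's trajectory table, clone ledger, final lattice snapshot
#' (gzip-compressed dense integer CSV) and a JSON manifest (parameters,
#' seed, regime classification, terminal cause) into a directory.
#'
#' @param sim a \code{tumor_sim}.
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest list.
#' @export
write_run_outputs <- function(sim, dir) {
  stopifnot(inherits(sim, "tumor_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$trajectory, file.path(dir, "trajectory.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(sim$ledger), file.path(dir, "clones.csv"),
                   row.names = FALSE)
  con <- gzfile(file.path(dir, "grid.csv.gz"), "w")
  utils::write.table(sim$state$grid, con, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  close(con)
  manifest <- list(
    package_version = as.character(utils::packageVersion("latticeshed")),
    params = unclass(sim$params),
    seed = sim$seed,
    record_every = sim$record_every,
    regime = regime(sim$params),
    terminal_cause = sim$status,
    final_size = sim$final_size,
    sweeps = sim$sweeps,
    detected = sim$detected,
    detection_sweep = sim$detection_sweep,
    center = sim$state$center
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Blood-vs-tissue bias report for a simulated run
#'
#' Assembles the distortion measures for one run at a set of sequencing
#' detection limits: per-clone blood-minus-tissue fraction differences at
#' the final state, inverse Simpson diversity in blood and tissue, and per
#' recorded sweep the detectable driver counts under biased and uniform
#' shedding with the resulting percent spatial bias.
#'
#' @param sim a \code{tumor_sim}.
#' @param cal a [shedding_calibration()] object.
#' @param sp a [scale_params()] object.
#' @param limits numeric vector of VAF detection limits.
#' @return List with \code{clone_differences}, \code{diversity}
#'   (named vector), and \code{detection}, a data frame with one row per
#'   (sweep, limit).
#' @export
bias_report <- function(sim, cal, sp = scale_params(),
                        limits = c(1e-3, 1e-2)) {
  counts <- region_counts(sim$state, sim$params$R)
  d <- effective_death_rates(sim$params, sim$detected)
  tis <- tissue_clone_fractions(counts)
  blo <- blood_clone_fractions(counts, d[1], d[2])
  cfd <- clone_fraction_differences(blo, tis)
  vtraj <- vaf_trajectory(sim, cal, sp)
  det <- do.call(rbind, lapply(limits, function(lim) {
    per_sweep <- lapply(split(vtraj, vtraj$sweep), function(vt) {
      nb <- count_detectable(vt$vaf_biased, lim)
      nu <- count_detectable(vt$vaf_unbiased, lim)
      data.frame(sweep = vt$sweep[1], limit = lim,
                 n_detect_biased = nb, n_detect_unbiased = nu,
                 percent_bias = percent_spatial_bias(nb, nu))
    })
    do.call(rbind, per_sweep)
  }))
  rownames(det) <- NULL
  list(
    clone_differences = cfd,
    diversity = c(tissue = inverse_simpson(tis), blood = inverse_simpson(blo)),
    detection = det
  )
}
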