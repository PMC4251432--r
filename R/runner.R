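#' Run a scenario and write all outputs to a directory
#'
#' Runs [run_simulation()] and writes the standard output set:
#' `species.csv`, `occupancy.csv`, `events.csv`, `metrics.csv` (the
#' snapshot table), `rates_by_region.csv` (final-time per-region mean tip
#' rates under both estimators), `phylogeny_extant.nwk` (when >= 2 species
#' are extant), `config.used.yaml` (the resolved configuration including
#' the seed actually used), and `run.log`.
#'
#' @param cfg A `scenario_config`.
#' @param dir Output directory (created if needed).
#' @param ... Passed to [run_simulation()].
#' @return The `simulation_result`, invisibly.
#' @export
run_scenario_dir <- function(cfg, dir, ...) {
  res <- run_simulation(cfg, ...)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(d, f) write.csv(d, file.path(dir, f), row.names = FALSE)
  wcsv(res$species, "species.csv")
  wcsv(res$occupancy, "occupancy.csv")
  wcsv(res$events, "events.csv")
  wcsv(res$snapshots, "metrics.csv")
  n_regions <- res$config$n_regions
  last <- res$snapshots[nrow(res$snapshots), ]
  rates <- data.frame(
    region = seq_len(n_regions),
    richness = as.numeric(last[paste0("richness_", seq_len(n_regions))]),
    es_rate = as.numeric(last[paste0("es_rate_", seq_len(n_regions))]),
    realized_rate =
      as.numeric(last[paste0("realized_rate_", seq_len(n_regions))])
  )
  wcsv(rates, "rates_by_region.csv")
  if (sum(is.na(res$species$extinction_time)) >= 2L) {
    tr <- extant_tree(res$species, res$final_time)
    writeLines(to_newick(tr), file.path(dir, "phylogeny_extant.nwk"))
  }
  write_scenario_config(res$config, file.path(dir, "config.used.yaml"))
  writeLines(res$log_lines, file.path(dir, "run.log"))
  invisible(res)
}

#' Derive the seed of replicate k from a base seed
#'
#' The documented counter scheme: `seed_k = base_seed + k - 1` (kept in
#' 31-bit integer range), so any single replicate can be reproduced in
#' isolation.
#'
#' @param base_seed Base seed (integer).
#' @param k Replicate index (1-based).
#' @return Integer seed.
#' @export
replicate_seed <- function(base_seed, k) {
  as.integer((as.numeric(base_seed) + k - 1) %% .Machine$integer.max)
}

#' Run replicate simulations and aggregate their metric trajectories
#'
#' Runs `n` independent replicates of one scenario with seeds derived from
#' `base_seed` by [replicate_seed()], and aggregates the snapshot metrics
#' over replicates on the common snapshot grid (mean, min, max per metric
#' per snapshot time).  A replicate that fails is recorded and excluded
#' from the aggregate with a warning.
#'
#' @param cfg A `scenario_config` (its `seed` field is ignored).
#' @param n Number of replicates (>= 1).
#' @param base_seed Base seed.
#' @param ... Passed to [run_simulation()].
#' @return A `replicate_set` list: `scenario`, `n`, `seeds`, `results`
#'   (list of `simulation_result`), `aggregate` (data frame with columns
#'   `time`, `metric`, `mean`, `min`, `max`, `n_replicates`), and
#'   `failures` (character).
#' @export
run_replicates <- function(cfg, n, base_seed, ...) {
  stopifnot(n >= 1)
  cfg <- validate_scenario_config(cfg)
  seeds <- vapply(seq_len(n), replicate_seed, integer(1),
                  base_seed = base_seed)
  results <- vector("list", n)
  failures <- character()
  for (k in seq_len(n)) {
    cfg_k <- cfg
    cfg_k$seed <- seeds[k]
    results[[k]] <- tryCatch(run_simulation(cfg_k, ...), error = function(e) {
      warning("replicate ", k, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(results[[k]])) {
      failures <- c(failures, paste0("replicate ", k, " (seed ", seeds[k], ")"))
    }
  }
  done <- results[!vapply(results, is.null, logical(1))]
  metrics <- c("richness", "r_lat_rich", "r_time_rich", "mrd_slope", "beta")
  agg <- NULL
  if (length(done)) {
    times <- Reduce(intersect, lapply(done, function(r) r$snapshots$time))
    rows <- list()
    for (m in metrics) {
      vals <- vapply(done, function(r) {
        s <- r$snapshots
        s[[m]][match(times, s$time)]
      }, numeric(length(times)))
      vals <- matrix(vals, nrow = length(times))
      rows[[m]] <- data.frame(
        time = times, metric = m,
        mean = rowMeans(vals, na.rm = TRUE),
        min = suppressWarnings(apply(vals, 1L, min, na.rm = TRUE)),
        max = suppressWarnings(apply(vals, 1L, max, na.rm = TRUE)),
        n_replicates = rowSums(!is.na(vals))
      )
    }
    agg <- do.call(rbind, rows)
    row.names(agg) <- NULL
  }
  structure(list(scenario = cfg$scenario, n = n, seeds = seeds,
                 results = results, aggregate = agg, failures = failures),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat("<replicate_set> ", x$scenario, ": ", x$n, " replicates (seeds ",
      paste(x$seeds, collapse = ", "), ")\n", sep = "")
  if (length(x$failures)) cat("  failed: ",
                              paste(x$failures, collapse = "; "), "\n")
  invisible(x)
}

.read_occupancy_csv <- function(path) {
  occ <- read.csv(path)
  need <- c("species_id", "region", "population", "colonization_time")
  missing <- setdiff(need, names(occ))
  if (length(missing)) {
    stop("occupancy table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  occ
}

#' Compute the diversity metrics from files
#'
#' The simulator-independent metrics path: reads a Newick tree and a long
#' occupancy table (`species_id`, `region`, `population`,
#' `colonization_time`) -- either written by [run_scenario_dir()] or
#' supplied externally -- and computes every diversity metric that does
#' not require the event log.  If `events` (an `events.csv` path) is
#' given, realized per-lineage rates are computed too, which additionally
#' requires `species` (a `species.csv` path).
#'
#' @param newick Path to a Newick file (tip labels = species ids).
#' @param occupancy Path to the occupancy CSV.
#' @param at_time Observation step; defaults to the tree depth (root to
#'   tip path length), which equals the observation step for trees written
#'   by the simulator with clade origin at step 0.
#' @param n_regions Number of gradient regions; defaults to the maximum
#'   region index in the occupancy table.
#' @param species,events Optional paths to `species.csv` / `events.csv`
#'   for the realized-rate columns.
#' @return One-row data frame as [metrics_snapshot()].
#' @export
metrics_from_files <- function(newick, occupancy, at_time = NULL,
                               n_regions = NULL, species = NULL,
                               events = NULL) {
  tree <- tryCatch(ape::read.tree(newick), error = function(e) {
    stop("failed to parse Newick file ", newick, ": ", conditionMessage(e))
  })
  if (is.null(tree)) stop("failed to parse Newick file ", newick)
  occ <- .read_occupancy_csv(occupancy)
  if (is.null(n_regions)) n_regions <- max(occ$region)
  if (is.null(at_time)) {
    depths <- ape::node.depth.edgelength(tree)
    at_time <- max(depths[seq_along(tree$tip.label)])
  }
  rich <- richness_by_region(occ, n_regions)
  durations <- region_occupancy_times(occ, at_time, n_regions)
  n_distinct <- length(unique(occ$species_id[occ$population > 0]))
  out <- data.frame(time = at_time, richness = n_distinct)
  out[paste0("richness_", seq_len(n_regions))] <- as.list(rich)
  out$r_lat_rich <- latitude_richness_correlation(rich)
  out$r_time_rich <- time_richness_correlation(durations, rich)
  out$mrd_slope <- mrd_richness_slope(tree, occ, n_regions)
  bm <- tryCatch(beta_ml(tree), error = function(e) NULL)
  out$beta <- if (is.null(bm)) NA_real_ else as.numeric(bm)
  out$beta_boundary <- if (is.null(bm)) NA else attr(bm, "boundary")
  es <- regional_mean_tip_rate(tree, occ, n_regions, "equal_splits")
  out[paste0("es_rate_", seq_len(n_regions))] <- as.list(es)
  realized <- rep(NA_real_, n_regions)
  if (!is.null(events)) {
    if (is.null(species)) {
      stop("realized rates from an event log also need the species table")
    }
    sp_df <- read.csv(species)
    ev_df <- read.csv(events)
    realized <- regional_mean_tip_rate(tree, occ, n_regions, "realized",
                                       species = sp_df, events = ev_df,
                                       at_time = at_time)
  }
  out[paste0("realized_rate_", seq_len(n_regions))] <- as.list(realized)
  out
}
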