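#' Regional species richness
#'
#' Count of species with population > 0 in each region.
#'
#' @param occupancy Long occupancy table (`species_id`, `region`,
#'   `population`, `colonization_time`).
#' @param n_regions Number of gradient regions.
#' @return Integer vector of length `n_regions`.
#' @export
richness_by_region <- function(occupancy, n_regions) {
  occ <- occupancy[occupancy$population > 0, , drop = FALSE]
  tabulate(occ$region, nbins = n_regions)
}

.pearson_or_na <- function(x, y) {
  if (length(x) < 3L) return(NA_real_)
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Latitude-richness correlation
#'
#' Pearson correlation between the region index (the latitude proxy:
#' region 1 = tropics, higher index = higher latitude) and regional
#' richness, over occupied regions only.  A value of -1 is the classical
#' latitudinal gradient (richness falling away from the tropics); +1 is a
#' reverse gradient.  Returns `NA` (undefined, never silently 0) with
#' fewer than 3 occupied regions or zero richness variance.
#'
#' @param richness Per-region richness vector (region 1 = tropics).
#' @return Pearson r, or `NA` if undefined.
#' @export
latitude_richness_correlation <- function(richness) {
  occ <- which(richness > 0)
  .pearson_or_na(occ, richness[occ])
}

#' Time a clade has occupied each region
#'
#' For each occupied region, `at_time` minus the earliest colonization
#' time among its extant resident species -- the occupancy time estimated
#' from extant members only, as an empiricist would from a phylogeny of
#' living species.  Unoccupied regions are `NA`.
#'
#' @param occupancy Long occupancy table of extant residencies.
#' @param at_time Observation step.
#' @param n_regions Number of gradient regions.
#' @return Numeric vector of durations (steps), `NA` where unoccupied.
#' @export
region_occupancy_times <- function(occupancy, at_time, n_regions) {
  occ <- occupancy[occupancy$population > 0, , drop = FALSE]
  out <- rep(NA_real_, n_regions)
  if (nrow(occ) == 0L) return(out)
  mins <- tapply(occ$colonization_time, occ$region, min)
  out[as.integer(names(mins))] <- at_time - mins
  out
}

#' Occupancy-time vs richness correlation
#'
#' Pearson correlation between how long each region has been occupied and
#' its current richness, over occupied regions (a positive value is the
#' time-for-speciation effect).  `NA` if fewer than 3 regions have defined
#' durations or either variable has zero variance.
#'
#' @param durations Per-region occupancy times ([region_occupancy_times()]).
#' @param richness Per-region richness.
#' @return Pearson r, or `NA` if undefined.
#' @export
time_richness_correlation <- function(durations, richness) {
  ok <- which(!is.na(durations) & richness > 0)
  .pearson_or_na(durations[ok], richness[ok])
}

#' Slope of scaled mean root distance on regional richness
#'
#' For each occupied region, the mean root distance (MRD) of its resident
#' extant species is computed from the extant tree and divided by the
#' maximum root distance of the whole tree (scaled MRD in (0, 1\]).  The
#' statistic is the OLS slope of scaled MRD (response) on richness
#' (predictor) across occupied regions -- a regression, not a correlation,
#' so swapping the roles of the variables changes the value.  `NA` if
#' fewer than 3 regions are occupied or richness has zero variance.
#'
#' @param tree Extant tree ([extant_tree()]); tip labels are species ids.
#' @param occupancy Long occupancy table of the same species.
#' @param n_regions Number of gradient regions.
#' @return OLS slope, or `NA` if undefined.
#' @export
mrd_richness_slope <- function(tree, occupancy, n_regions) {
  rd <- root_distances(tree)
  occ <- occupancy[occupancy$population > 0, , drop = FALSE]
  rd_sp <- rd[as.character(occ$species_id)]
  mrd <- tapply(rd_sp, occ$region, mean) / max(rd)
  rich <- richness_by_region(occ, n_regions)
  regions <- as.integer(names(mrd))
  y <- as.numeric(mrd)
  x <- rich[regions]
  if (length(x) < 3L || sd(x) == 0) return(NA_real_)
  unname(coef(lm(y ~ x))[2L])
}

#' Mean tip speciation rate per region
#'
#' Averages tip-level speciation-rate estimates over the species present
#' in each region (a species present in several regions contributes to
#' each).  Two estimators are available: `"equal_splits"`, the
#' phylogeny-only DR statistic ([equal_splits_rate()]), and `"realized"`,
#' the per-lineage event count from the simulator's event log
#' ([lineage_event_rate()]).
#'
#' @param tree Extant tree (tip labels = species ids); required for both
#'   estimators.
#' @param occupancy Long occupancy table.
#' @param n_regions Number of gradient regions.
#' @param estimator `"equal_splits"` or `"realized"`.
#' @param species,events,at_time Species table, event log and observation
#'   step; required for the `"realized"` estimator.
#' @return Numeric vector of per-region mean rates; `NA` where unoccupied.
#' @export
regional_mean_tip_rate <- function(tree, occupancy, n_regions,
                                   estimator = c("equal_splits", "realized"),
                                   species = NULL, events = NULL,
                                   at_time = NULL) {
  estimator <- match.arg(estimator)
  if (estimator == "equal_splits") {
    rates <- equal_splits_rate(tree)
  } else {
    if (is.null(species) || is.null(events) || is.null(at_time)) {
      stop("the realized estimator needs 'species', 'events' and 'at_time'")
    }
    rates <- .realized_tip_rates(species, events, at_time)
  }
  occ <- occupancy[occupancy$population > 0, , drop = FALSE]
  r_sp <- rates[as.character(occ$species_id)]
  if (anyNA(r_sp)) stop("rates are missing for some resident species")
  out <- rep(NA_real_, n_regions)
  means <- tapply(r_sp, occ$region, mean)
  out[as.integer(names(means))] <- means
  out
}

# snapshot from a live sim_state (internal; drives run_simulation)
metrics_snapshot_state <- function(S, tree_stats = TRUE) {
  species <- .state_species_df(S)
  occupancy <- .state_occupancy_df(S)
  events <- if (tree_stats) .state_events_df(S) else NULL
  metrics_snapshot(species, occupancy, S$t, S$cfg$n_regions,
                   events = events, tree_stats = tree_stats)
}

#' Compute one diagnostic snapshot
#'
#' Bundles the multi-pattern fingerprint at one time point: per-region
#' richness, the latitude-richness and occupancy-time-richness Pearson
#' correlations, the scaled MRD-richness OLS slope, the beta imbalance ML
#' estimate, and per-region mean tip rates under both estimators.
#' Statistics that are undefined at this time point (too few species or
#' occupied regions, zero variance) are `NA`.
#'
#' @param species Species table.
#' @param occupancy Long occupancy table of extant residencies.
#' @param at_time Observation step.
#' @param n_regions Number of gradient regions.
#' @param events Event log (needed for the realized rate columns; omit to
#'   skip them).
#' @param tree_stats If `FALSE`, skip all tree-based statistics.
#' @return A one-row data frame: `time`, `richness` (count of extant
#'   species),
#'   `richness_1` ... `richness_R`, `r_lat_rich`, `r_time_rich`,
#'   `mrd_slope`, `beta`, `beta_boundary`, `es_rate_1` ... `es_rate_R`,
#'   `realized_rate_1` ... `realized_rate_R`.
#' @export
metrics_snapshot <- function(species, occupancy, at_time, n_regions,
                             events = NULL, tree_stats = TRUE) {
  rich <- richness_by_region(occupancy, n_regions)
  durations <- region_occupancy_times(occupancy, at_time, n_regions)
  r_lat <- latitude_richness_correlation(rich)
  r_time <- time_richness_correlation(durations, rich)
  mrd <- NA_real_
  beta <- NA_real_
  beta_boundary <- NA
  es <- rep(NA_real_, n_regions)
  realized <- rep(NA_real_, n_regions)
  n_extant <- sum(species$origin_time <= at_time &
                    (is.na(species$extinction_time) |
                       species$extinction_time > at_time))
  if (tree_stats && n_extant >= 3L) {
    tree <- extant_tree(species, at_time)
    mrd <- mrd_richness_slope(tree, occupancy, n_regions)
    bm <- tryCatch(beta_ml(tree), error = function(e) NULL)
    if (!is.null(bm)) {
      beta <- as.numeric(bm)
      beta_boundary <- attr(bm, "boundary")
    }
    es <- regional_mean_tip_rate(tree, occupancy, n_regions, "equal_splits")
    if (!is.null(events) && at_time > 0) {
      realized <- regional_mean_tip_rate(tree, occupancy, n_regions,
                                         "realized", species = species,
                                         events = events, at_time = at_time)
    }
  }
  out <- data.frame(time = at_time, richness = n_extant)
  out[paste0("richness_", seq_len(n_regions))] <- as.list(rich)
  out$r_lat_rich <- r_lat
  out$r_time_rich <- r_time
  out$mrd_slope <- mrd
  out$beta <- beta
  out$beta_boundary <- beta_boundary
  out[paste0("es_rate_", seq_len(n_regions))] <- as.list(es)
  out[paste0("realized_rate_", seq_len(n_regions))] <- as.list(realized)
  out
}
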