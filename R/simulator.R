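#' Gaussian environmental-filter weight
#'
#' Performance of a species with thermal optimum `trait` in a region with
#' environment `env`: `exp(-(trait - env)^2 / (2 * omega^2))`.  The weight
#' is 1 at a perfect match and decays symmetrically with the mismatch;
#' `omega` (degrees C) sets the width of the filter.
#'
#' @param trait Thermal optimum (degrees C); vectorized.
#' @param env Regional environment (degrees C); vectorized.
#' @param omega Filter SD (degrees C); must be > 0.
#' @return Weights in (0, 1].
#' @examples
#' fitness_weight(20, 20, 3)            # 1
#' fitness_weight(23, 20, 3)            # exp(-1/2)
#' @export
fitness_weight <- function(trait, env, omega) {
  if (!is.numeric(omega) || length(omega) != 1L || is.na(omega) || omega <= 0) {
    stop("'omega' must be a single positive number")
  }
  exp(-((trait - env)^2) / (2 * omega^2))
}

# ---------------------------------------------------------------------------
# Simulation state
#
# The state is an environment (reference semantics: the per-step operators
# mutate it in place).  Species arrays are indexed by species_id and grown
# by doubling; `act` holds the ids of extant species.  Matrices are
# species x region.
# ---------------------------------------------------------------------------

#' Create an initial simulation state
#'
#' Sets up the founder: species 1 with thermal optimum equal to the
#' environment of `origin_region`, resident there with colonization time 0.
#' Populations are assigned by the first allocation of step 1.
#'
#' @param cfg A validated `scenario_config`.
#' @return A `sim_state` environment, mutated in place by the step
#'   operators ([allocate_populations()], [disturbance_step()],
#'   [speciation_step()], [dispersal_step()], [extinction_step()]).
#' @export
new_sim_state <- function(cfg) {
  cfg <- validate_scenario_config(cfg)
  R <- cfg$n_regions
  cap <- 256L
  S <- new.env(parent = emptyenv())
  S$cfg <- cfg
  S$t <- 0L
  S$cap <- cap
  S$n_sp <- 1L
  S$trait <- c(cfg$env_values[cfg$origin_region], numeric(cap - 1L))
  S$parent <- rep(NA_integer_, cap)
  S$origin_t <- c(0L, rep(NA_integer_, cap - 1L))
  S$extinct_t <- rep(NA_integer_, cap)
  S$alive <- c(TRUE, rep(FALSE, cap - 1L))
  S$resident <- matrix(FALSE, cap, R)
  S$resident[1L, cfg$origin_region] <- TRUE
  S$pop <- matrix(0, cap, R)
  S$col_t <- matrix(NA_real_, cap, R)
  S$col_t[1L, cfg$origin_region] <- 0
  S$act <- 1L
  # event log buffers (append-only, grown by doubling)
  S$ev_cap <- 4096L
  S$ev_n <- 0L
  S$ev_time <- integer(S$ev_cap)
  S$ev_type <- integer(S$ev_cap)   # 1 spec, 2 col, 3 locext, 4 globext, 5 dist
  S$ev_region <- integer(S$ev_cap)
  S$ev_sp <- integer(S$ev_cap)
  S$ev_child <- integer(S$ev_cap)
  S$n_speciations <- 0L
  S$n_global_ext <- 0L
  S$exposure <- numeric(R)         # cumulative individual-steps per region
  S$spec_events_region <- numeric(R)
  S$snapshots <- list()
  S$log_lines <- character()
  S
}

.ev_type_labels <- c("speciation", "colonization", "local_extinction",
                     "global_extinction", "disturbance")

.log_ev <- function(S, time, type, region, sp, child = NA_integer_) {
  n <- length(time)
  if (n == 0L) return(invisible())
  need <- S$ev_n + n
  if (need > S$ev_cap) {
    new_cap <- max(S$ev_cap * 2L, need)
    grow <- function(v) { length(v) <- new_cap; v }
    S$ev_time <- grow(S$ev_time); S$ev_type <- grow(S$ev_type)
    S$ev_region <- grow(S$ev_region); S$ev_sp <- grow(S$ev_sp)
    S$ev_child <- grow(S$ev_child)
    S$ev_cap <- new_cap
  }
  idx <- (S$ev_n + 1L):need
  S$ev_time[idx] <- time
  S$ev_type[idx] <- type
  S$ev_region[idx] <- region
  S$ev_sp[idx] <- sp
  S$ev_child[idx] <- child
  S$ev_n <- need
  invisible()
}

.grow_species <- function(S, need) {
  if (need <= S$cap) return(invisible())
  new_cap <- max(S$cap * 2L, need)
  R <- S$cfg$n_regions
  add <- new_cap - S$cap
  S$trait <- c(S$trait, numeric(add))
  S$parent <- c(S$parent, rep(NA_integer_, add))
  S$origin_t <- c(S$origin_t, rep(NA_integer_, add))
  S$extinct_t <- c(S$extinct_t, rep(NA_integer_, add))
  S$alive <- c(S$alive, rep(FALSE, add))
  S$resident <- rbind(S$resident, matrix(FALSE, add, R))
  S$pop <- rbind(S$pop, matrix(0, add, R))
  S$col_t <- rbind(S$col_t, matrix(NA_real_, add, R))
  S$cap <- new_cap
  invisible()
}

# occupied (species, region) cells among extant species, ordered by
# (species_id, region) -- the fixed draw order of the run
.resident_cells <- function(S, positive_pop = FALSE) {
  act <- S$act
  if (length(act) == 0L) {
    return(list(sp = integer(), rg = integer()))
  }
  m <- if (positive_pop) S$pop[act, , drop = FALSE] > 0 else
    S$resident[act, , drop = FALSE]
  cells <- which(m, arr.ind = TRUE, useNames = FALSE)
  if (nrow(cells) == 0L) return(list(sp = integer(), rg = integer()))
  sp <- act[cells[, 1L]]
  rg <- cells[, 2L]
  o <- order(sp, rg)
  list(sp = sp[o], rg = rg[o])
}

# drop species (ids) from regions (vector-parallel); logs local extinctions
# and any resulting global extinctions at time `t`
.local_extinguish <- function(S, sp, rg, t) {
  if (length(sp) == 0L) return(invisible())
  idx <- cbind(sp, rg)
  S$resident[idx] <- FALSE
  S$pop[idx] <- 0
  S$col_t[idx] <- NA_real_
  .log_ev(S, rep.int(t, length(sp)), 3L, rg, sp)
  u <- unique(sp)
  gone <- u[rowSums(S$resident[u, , drop = FALSE]) == 0]
  if (length(gone)) {
    gone <- sort(gone)
    S$alive[gone] <- FALSE
    S$extinct_t[gone] <- t
    S$act <- setdiff(S$act, gone)
    S$n_global_ext <- S$n_global_ext + length(gone)
    .log_ev(S, rep.int(t, length(gone)), 4L, rep(NA_integer_, length(gone)),
            gone)
  }
  invisible()
}

#' Allocate regional populations from filter weights
#'
#' Recomputes every resident population for the current step.  In zero-sum
#' mode each region's carrying capacity `K[k]` is divided among its
#' resident species in proportion to their environmental-filter weights:
#' `N_ik = round(K_k * w_ik / sum_j w_jk)` (round-half-to-even, with a
#' deterministic repair that decrements the largest populations if rounding
#' overshoots `K_k`, so `sum_i N_ik <= K_k` always holds).  Without the
#' zero-sum constraint each species independently attains
#' `N_ik = round(K_k * w_ik)`.  A species whose population rounds to zero
#' is immediately locally extinct.
#'
#' @param S A `sim_state`, modified in place.
#' @return The state, invisibly.
#' @export
allocate_populations <- function(S) {
  cfg <- S$cfg
  cells <- .resident_cells(S)
  sp <- cells$sp; rg <- cells$rg
  if (length(sp) == 0L) return(invisible(S))
  w <- fitness_weight(S$trait[sp], cfg$env_values[rg], cfg$omega)
  if (cfg$zero_sum) {
    sums <- rowsum(w, rg)                       # sorted by unique region
    sw <- numeric(cfg$n_regions)
    sw[as.integer(rownames(sums))] <- sums[, 1L]
    newpop <- round(cfg$K[rg] * w / sw[rg])
    # overflow repair: rounding may exceed K in a region; decrement the
    # largest populations (ties: smaller species_id first) until it fits
    tots <- rowsum(newpop, rg)
    over <- as.integer(rownames(tots))[tots[, 1L] > cfg$K[as.integer(rownames(tots))]]
    for (k in over) {
      in_k <- which(rg == k)
      excess <- sum(newpop[in_k]) - cfg$K[k]
      o <- in_k[order(-newpop[in_k], sp[in_k])]
      j <- 1L
      while (excess > 0) {
        if (newpop[o[j]] > 0) {
          newpop[o[j]] <- newpop[o[j]] - 1
          excess <- excess - 1
        }
        j <- if (j == length(o)) 1L else j + 1L
      }
    }
  } else {
    newpop <- round(cfg$K[rg] * w)
  }
  act <- S$act
  S$pop[act, ] <- 0
  S$pop[cbind(sp, rg)] <- newpop
  zero <- newpop == 0
  if (any(zero)) .local_extinguish(S, sp[zero], rg[zero], S$t)
  invisible(S)
}

#' Apply one pulsed disturbance
#'
#' In every region `k`, populations are reduced to
#' `round(N * (1 - m_k))` where `m_k` is the per-region disturbance
#' magnitude (fraction of individuals killed).  Applied after allocation
#' and before the extinction draw of the same step; one disturbance event
#' is logged per region.  Species whose population drops to zero are
#' locally extinct.
#'
#' @param S A `sim_state`, modified in place.
#' @return The state, invisibly.
#' @export
disturbance_step <- function(S) {
  cfg <- S$cfg
  cells <- .resident_cells(S, positive_pop = TRUE)
  sp <- cells$sp; rg <- cells$rg
  .log_ev(S, rep.int(S$t, cfg$n_regions), 5L, seq_len(cfg$n_regions),
          rep(NA_integer_, cfg$n_regions))
  if (length(sp) == 0L) return(invisible(S))
  idx <- cbind(sp, rg)
  newpop <- round(S$pop[idx] * (1 - cfg$disturbance_magnitude[rg]))
  S$pop[idx] <- newpop
  zero <- newpop == 0
  if (any(zero)) .local_extinguish(S, sp[zero], rg[zero], S$t)
  invisible(S)
}

#' Draw speciation events for one step
#'
#' Every occupied cell (species i, region k) with population `N` draws a
#' number of daughter species from `Binomial(N, p_speciation[k])`.  Each
#' daughter inherits the parent's thermal optimum perturbed by
#' `Normal(0, sigma_E)` (niche conservatism), is resident only in the
#' parent's region with colonization time = the current step, and enters
#' the allocation pool the following step.
#'
#' @param S A `sim_state`, modified in place.
#' @return The state, invisibly.
#' @export
speciation_step <- function(S) {
  cfg <- S$cfg
  cells <- .resident_cells(S, positive_pop = TRUE)
  sp <- cells$sp; rg <- cells$rg
  if (length(sp) == 0L) return(invisible(S))
  N <- S$pop[cbind(sp, rg)]
  n_ev <- rbinom(length(sp), N, cfg$p_speciation[rg])
  tot <- sum(n_ev)
  if (tot == 0L) return(invisible(S))
  parents <- rep.int(sp, n_ev)
  regs <- rep.int(rg, n_ev)
  ids <- S$n_sp + seq_len(tot)
  .grow_species(S, S$n_sp + tot)
  S$trait[ids] <- S$trait[parents] + rnorm(tot, 0, cfg$sigma_E)
  S$parent[ids] <- parents
  S$origin_t[ids] <- S$t
  S$alive[ids] <- TRUE
  S$resident[cbind(ids, regs)] <- TRUE
  S$col_t[cbind(ids, regs)] <- S$t
  S$n_sp <- S$n_sp + tot
  S$act <- c(S$act, ids)
  S$n_speciations <- S$n_speciations + tot
  S$spec_events_region[] <- S$spec_events_region +
    tabulate(regs, nbins = cfg$n_regions)
  .log_ev(S, rep.int(S$t, tot), 1L, regs, parents, ids)
  invisible(S)
}

#' Draw dispersal (colonization) events for one step
#'
#' For each occupied cell (i, k) with population `N` and each adjacent
#' region `k'` where species i is currently absent, i colonizes `k'` with
#' probability `1 - (1 - p_dispersal)^N` (at least one of `N` independent
#' per-individual emigration attempts succeeds).  Boundary regions have a
#' single neighbor.  Colonists enter the allocation pool of the next step;
#' colonization time is the current step.
#'
#' @param S A `sim_state`, modified in place.
#' @return The state, invisibly.
#' @export
dispersal_step <- function(S) {
  cfg <- S$cfg
  if (cfg$p_dispersal <= 0) return(invisible(S))
  cells <- .resident_cells(S, positive_pop = TRUE)
  sp <- cells$sp; rg <- cells$rg
  if (length(sp) == 0L) return(invisible(S))
  # candidate (source cell, target) pairs, fixed order (species, region, tgt)
  sp2 <- c(sp, sp); rg2 <- c(rg, rg)
  tgt <- c(rg - 1L, rg + 1L)
  keep <- tgt >= 1L & tgt <= cfg$n_regions
  sp2 <- sp2[keep]; rg2 <- rg2[keep]; tgt <- tgt[keep]
  absent <- !S$resident[cbind(sp2, tgt)]
  sp2 <- sp2[absent]; rg2 <- rg2[absent]; tgt <- tgt[absent]
  if (length(sp2) == 0L) return(invisible(S))
  o <- order(sp2, rg2, tgt)
  sp2 <- sp2[o]; rg2 <- rg2[o]; tgt <- tgt[o]
  N <- S$pop[cbind(sp2, rg2)]
  p_col <- 1 - (1 - cfg$p_dispersal)^N
  hit <- runif(length(sp2)) < p_col
  if (!any(hit)) return(invisible(S))
  hsp <- sp2[hit]; htg <- tgt[hit]
  dup <- duplicated(cbind(hsp, htg))   # two sources into the same target
  hsp <- hsp[!dup]; htg <- htg[!dup]
  S$resident[cbind(hsp, htg)] <- TRUE
  S$col_t[cbind(hsp, htg)] <- S$t
  .log_ev(S, rep.int(S$t, length(hsp)), 2L, htg, hsp)
  invisible(S)
}

#' Draw stochastic extinctions for one step
#'
#' Each occupied cell (i, k) with population `N > 0` goes locally extinct
#' with probability `exp(-alpha_ext * N)` -- a negative exponential of
#' population size, so small populations are at high risk and large ones
#' essentially safe.  A species left with no occupied region is globally
#' extinct (extinction time = current step) and never resurrects.
#'
#' @param S A `sim_state`, modified in place.
#' @return The state, invisibly.
#' @export
extinction_step <- function(S) {
  cfg <- S$cfg
  cells <- .resident_cells(S, positive_pop = TRUE)
  sp <- cells$sp; rg <- cells$rg
  if (length(sp) == 0L) return(invisible(S))
  N <- S$pop[cbind(sp, rg)]
  p_ext <- exp(-cfg$alpha_ext * N)
  die <- runif(length(sp)) < p_ext
  if (any(die)) .local_extinguish(S, sp[die], rg[die], S$t)
  invisible(S)
}

.state_species_df <- function(S) {
  ids <- seq_len(S$n_sp)
  data.frame(
    species_id = ids,
    parent_id = S$parent[ids],
    origin_time = S$origin_t[ids],
    extinction_time = S$extinct_t[ids],
    trait = S$trait[ids]
  )
}

.state_events_df <- function(S) {
  idx <- seq_len(S$ev_n)
  data.frame(
    time = S$ev_time[idx],
    type = .ev_type_labels[S$ev_type[idx]],
    region = S$ev_region[idx],
    species_id = S$ev_sp[idx],
    child_id = S$ev_child[idx]
  )
}

.state_occupancy_df <- function(S) {
  cells <- .resident_cells(S)
  data.frame(
    species_id = cells$sp,
    region = cells$rg,
    population = S$pop[cbind(cells$sp, cells$rg)],
    colonization_time = S$col_t[cbind(cells$sp, cells$rg)]
  )
}

#' Run one full simulation
#'
#' Executes the per-step cycle (1) population allocation, (2) pulsed
#' disturbance when scheduled, (3) speciation, (4) dispersal,
#' (5) extinction, until `max_steps` is reached or extant richness
#' exceeds `max_species`.  Diagnostic snapshots ([metrics_snapshot()]) are
#' recorded every `snapshot_interval` steps and at the final step.
#' Identical configuration and seed give a bit-identical result.
#'
#' @param cfg A `scenario_config`.  If `cfg$seed` is `NA` a seed is drawn
#'   and recorded in the result.
#' @param check_invariants If `TRUE`, assert the zero-sum constraint
#'   (`sum_i N_ik <= K_k`) and bookkeeping closure
#'   (extant = speciations + 1 - global extinctions) after every step,
#'   stopping at the first violation.
#' @param snapshot_metrics If `FALSE`, snapshots record only the per-region
#'   richness and correlation metrics, skipping the tree-shape statistics
#'   (useful for long exploratory runs).
#' @return A `simulation_result` list: `species` (one row per species ever
#'   born), `occupancy` (long table of extant residencies with population
#'   and colonization time), `events` (the event log), `snapshots` (one row
#'   per snapshot, see [metrics_snapshot()]), `exposure` (cumulative
#'   individual-steps per region), `spec_events_region` (speciation event
#'   counts per region), `config`, `seed`, `final_time`, and
#'   `clade_extinct` (flag: the whole clade died).
#' @export
run_simulation <- function(cfg, check_invariants = FALSE,
                           snapshot_metrics = TRUE) {
  cfg <- validate_scenario_config(cfg)
  if (is.na(cfg$seed)) cfg$seed <- sample.int(.Machine$integer.max, 1L)
  set.seed(cfg$seed)
  S <- new_sim_state(cfg)
  freq <- cfg$disturbance_frequency
  t <- 0L
  while (t < cfg$max_steps) {
    t <- t + 1L
    S$t <- t
    allocate_populations(S)
    if (freq > 0 && t %% freq == 0L) disturbance_step(S)
    S$exposure[] <- S$exposure + colSums(S$pop[S$act, , drop = FALSE])
    speciation_step(S)
    dispersal_step(S)
    extinction_step(S)
    if (check_invariants) .check_state_invariants(S)
    if (t %% cfg$snapshot_interval == 0L) {
      S$snapshots[[length(S$snapshots) + 1L]] <-
        metrics_snapshot_state(S, tree_stats = snapshot_metrics)
    }
    if (t %% 1000L == 0L) {
      S$log_lines <- c(S$log_lines, sprintf(
        "step=%d richness=%d speciations=%d global_extinctions=%d",
        t, length(S$act), S$n_speciations, S$n_global_ext))
    }
    if (length(S$act) == 0L || length(S$act) > cfg$max_species) break
  }
  if (t %% cfg$snapshot_interval != 0L || length(S$snapshots) == 0L) {
    S$snapshots[[length(S$snapshots) + 1L]] <-
      metrics_snapshot_state(S, tree_stats = snapshot_metrics)
  }
  res <- list(
    species = .state_species_df(S),
    occupancy = .state_occupancy_df(S),
    events = .state_events_df(S),
    snapshots = do.call(rbind, S$snapshots),
    exposure = S$exposure,
    spec_events_region = S$spec_events_region,
    config = cfg,
    seed = cfg$seed,
    final_time = t,
    clade_extinct = length(S$act) == 0L,
    log_lines = S$log_lines
  )
  class(res) <- "simulation_result"
  res
}

.check_state_invariants <- function(S) {
  cfg <- S$cfg
  if (cfg$zero_sum) {
    tot <- colSums(S$pop[S$act, , drop = FALSE])
    if (any(tot > cfg$K + 1e-9)) {
      stop("zero-sum violation at step ", S$t, ": region totals ",
           paste(round(tot), collapse = " "))
    }
  }
  if (length(S$act) != S$n_speciations + 1L - S$n_global_ext) {
    stop("bookkeeping closure violated at step ", S$t)
  }
  invisible()
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result> scenario ", x$config$scenario,
      ", seed ", x$seed, "\n", sep = "")
  cat("  stopped at step ", x$final_time, " with ",
      sum(is.na(x$species$extinction_time)), " extant / ",
      nrow(x$species), " total species",
      if (x$clade_extinct) " (clade extinct)", "\n", sep = "")
  cat("  ", nrow(x$events), " events, ", nrow(x$snapshots),
      " snapshots\n", sep = "")
  invisible(x)
}
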