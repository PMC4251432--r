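test_that("the environmental filter weight follows the Gaussian closed form", {
  expect_equal(fitness_weight(20, 20, 3), 1)
  expect_equal(fitness_weight(23, 20, 3), exp(-0.5))
  expect_equal(fitness_weight(17, 20, 3), exp(-0.5))     # symmetry
  expect_equal(fitness_weight(30, 20, 5), fitness_weight(10, 20, 5))
  expect_error(fitness_weight(1, 2, 0), "omega")
  expect_error(fitness_weight(1, 2, -3), "omega")
})

test_that("zero-sum allocation splits K by relative weight and conserves it", {
  cfg <- scenario_preset("speciation", "tropical", seed = 1L)   # K = 22000
  # one species alone takes the whole capacity whatever its weight
  S <- fab_state(cfg, traits = 10, regions = 3L, pops = 0)
  allocate_populations(S)
  expect_equal(S$pop[1L, 3L], 22000)
  # two species with equal traits split it evenly
  S <- fab_state(cfg, traits = c(25, 25), regions = c(1L, 1L), pops = c(0, 0))
  allocate_populations(S)
  expect_equal(unname(S$pop[, 1L]), c(11000, 11000))
  # unequal weights: shares proportional to weights, total <= K
  S <- fab_state(cfg, traits = c(40, 36), regions = c(1L, 1L), pops = c(0, 0))
  allocate_populations(S)
  w <- fitness_weight(c(40, 36), 40, cfg$omega)
  expect_equal(unname(S$pop[, 1L]), round(22000 * w / sum(w)))
  expect_lte(sum(S$pop[, 1L]), 22000)
})

test_that("without the zero-sum constraint species attain populations independently", {
  cfg <- scenario_preset("pure_nc", "tropical", seed = 1L)      # K = 40000
  S <- fab_state(cfg, traits = c(40, 40), regions = c(1L, 1L), pops = c(0, 0))
  allocate_populations(S)
  expect_equal(unname(S$pop[, 1L]), c(40000, 40000))
  expect_gt(sum(S$pop[, 1L]), 40000)   # no energetic limit
})

test_that("a population that rounds to zero is an immediate local extinction", {
  cfg <- scenario_preset("pure_nc", "tropical", seed = 1L)
  S <- fab_state(cfg, traits = c(40, 0), regions = c(1L, 1L), pops = c(0, 0))
  allocate_populations(S)
  expect_false(S$resident[2L, 1L])
  expect_false(S$alive[2L])            # nowhere else to live
  ev <- ldgsim:::.state_events_df(S)
  expect_true(any(ev$type == "local_extinction" & ev$species_id == 2))
  expect_true(any(ev$type == "global_extinction" & ev$species_id == 2))
})

test_that("speciation event counts match binomial moments", {
  cfg <- scenario_preset("pure_nc", "tropical", seed = 99L)
  m <- 1e5
  set.seed(7)
  S <- fab_state(cfg, traits = rep(40, m), regions = rep(1L, m),
                 pops = rep(40000, m))
  speciation_step(S)     # one Binomial(40000, 1e-6) draw per species
  mean_events <- (S$n_sp - m) / m
  p_event <- 40000 * 1e-6
  se <- sqrt(p_event * (1 - 1e-6) / m)
  expect_lt(abs(mean_events - 0.04), 3 * se)
})

test_that("daughter traits deviate from the parent by Normal(0, sigma_E)", {
  cfg <- scenario_preset("pure_nc", "tropical", seed = 5L)
  m <- 10000
  set.seed(8)
  S <- fab_state(cfg, traits = rep(20, m), regions = rep(1L, m),
                 pops = rep(100, m))
  S$cfg$p_speciation <- rep(0.01, 10)   # ~1 daughter per parent
  speciation_step(S)
  kids <- (m + 1L):S$n_sp
  expect_gt(length(kids), 5000)
  dev <- S$trait[kids] - 20
  expect_lt(abs(sd(dev) - cfg$sigma_E) / cfg$sigma_E, 0.05)
  expect_lt(abs(mean(dev)), 3 * cfg$sigma_E / sqrt(length(kids)))
  # daughters are resident only in the parent's region, colonized now
  expect_true(all(S$resident[kids, 1L]))
  expect_equal(sum(S$resident[kids, ]), length(kids))
})

test_that("zero speciation and dispersal rates freeze the clade", {
  cfg <- scenario_preset("pure_nc", "tropical", seed = 3L,
                         p_speciation = 0, p_dispersal = 0, max_steps = 100L)
  res <- run_simulation(cfg)
  expect_equal(nrow(res$species), 1L)
  expect_equal(sum(is.na(res$species$extinction_time)), 1L)
  expect_equal(nrow(res$events), 0L)
  expect_equal(unique(res$occupancy$region), 1L)
})

test_that("colonization frequency matches 1 - (1 - p)^N", {
  cfg <- scenario_preset("pure_nc", "tropical", seed = 2L,
                         p_dispersal = 1e-3)
  m <- 10000
  set.seed(9)
  S <- fab_state(cfg, traits = rep(38, m), regions = rep(2L, m),
                 pops = rep(500, m))
  dispersal_step(S)
  p_col <- 1 - (1 - 1e-3)^500
  # each species had two independent chances (regions 1 and 3)
  freq <- sum(S$resident[, c(1L, 3L)]) / (2 * m)
  se <- sqrt(p_col * (1 - p_col) / (2 * m))
  expect_lt(abs(freq - p_col), 3 * se)
  # colonization times recorded at the current step
  ev <- ldgsim:::.state_events_df(S)
  expect_true(all(ev$time[ev$type == "colonization"] == S$t))
})

test_that("a species present everywhere has nothing to colonize", {
  cfg <- scenario_preset("pure_nc", "tropical", seed = 2L, p_dispersal = 0.5)
  S <- fab_state(cfg, traits = 20, regions = 1L, pops = 1000)
  S$resident[1L, ] <- TRUE
  S$pop[1L, ] <- 1000
  dispersal_step(S)
  expect_equal(ldgsim:::.state_events_df(S)$type, character(0))
})

test_that("local extinction frequency matches exp(-alpha * N)", {
  cfg <- scenario_preset("pure_nc", "tropical", seed = 4L)  # alpha = 0.01
  m <- 1e5
  set.seed(10)
  S <- fab_state(cfg, traits = rep(40, m), regions = rep(1L, m),
                 pops = rep(500, m))
  extinction_step(S)
  p_ext <- exp(-0.01 * 500)
  frac_dead <- sum(!S$alive[seq_len(m)]) / m
  se <- sqrt(p_ext * (1 - p_ext) / m)
  expect_lt(abs(frac_dead - p_ext), 3 * se)
})

test_that("disturbance removes the configured fraction of individuals", {
  cfg <- scenario_preset("disturbance", "tropical", seed = 1L)
  cfg$disturbance_magnitude <- c(0.75, 0.99, 0, rep(0.5, 7))
  S <- fab_state(cfg, traits = c(40, 36, 31), regions = c(1L, 2L, 3L),
                 pops = c(1000, 1000, 1000))
  S$t <- 100L
  disturbance_step(S)
  expect_equal(S$pop[1L, 1L], 250)   # 75% killed
  expect_equal(S$pop[2L, 2L], 10)    # 99% killed
  expect_equal(S$pop[3L, 3L], 1000)  # magnitude 0
  ev <- ldgsim:::.state_events_df(S)
  expect_equal(sum(ev$type == "disturbance"), cfg$n_regions)
})

test_that("identical config and seed give bit-identical results", {
  cfg <- scenario_preset("disturbance", "tropical", seed = 7L,
                         max_steps = 1500L)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$events, b$events)
  expect_identical(a$species, b$species)
  expect_identical(a$occupancy, b$occupancy)
  expect_identical(a$snapshots, b$snapshots)
})

test_that("zero-sum conservation and bookkeeping closure hold over 5000 steps", {
  cfg <- scenario_preset("energy", "tropical", seed = 21L, max_steps = 5000L)
  # check_invariants asserts sum_i N_ik <= K_k and
  # extant = speciations + 1 - global extinctions after every single step
  res <- run_simulation(cfg, check_invariants = TRUE)
  expect_s3_class(res, "simulation_result")
  # near-equality at the final state: every occupied region is filled to
  # within rounding slack (half the resident count)
  tot <- tapply(res$occupancy$population, res$occupancy$region, sum)
  nsp <- tapply(res$occupancy$population, res$occupancy$region, length)
  k <- res$config$K[as.integer(names(tot))]
  expect_true(all(tot <= k))
  expect_true(all(k - tot <= nsp / 2 + 1))
  # last snapshot richness equals the extant species count
  last <- res$snapshots[nrow(res$snapshots), ]
  expect_equal(last$richness, sum(is.na(res$species$extinction_time)))
})

test_that("pure niche conservatism gives near-exponential richness growth", {
  cfg <- scenario_preset("pure_nc", "tropical", seed = 31L,
                         max_species = 2000, snapshot_interval = 10L)
  res <- run_simulation(cfg, snapshot_metrics = FALSE)
  s <- res$snapshots[res$snapshots$richness >= 2, ]
  fit <- lm(log(richness) ~ time, data = s)
  expect_gt(summary(fit)$r.squared, 0.95)
})

test_that("realized per-capita speciation rates recover p_speciation", {
  res <- cached_run("speciation", "tropical", seed = 41L, steps = 3000L)
  events <- res$spec_events_region
  exposure <- res$exposure
  p <- res$config$p_speciation
  ok <- events >= 20
  expect_gt(sum(ok), 4)    # enough regions with decent counts
  rate <- events[ok] / exposure[ok]
  se <- sqrt(events[ok]) / exposure[ok]
  expect_true(all(abs(rate - p[ok]) <= 3 * se))
})

test_that("disturbance drives higher turnover in temperate than tropical regions", {
  res <- cached_run("disturbance", "tropical", ACC_SEEDS[1])
  half <- res$final_time / 2
  ev <- res$events
  # attribute each global extinction to the region(s) lost at death
  dead <- ev[ev$type == "global_extinction" & ev$time > half, ]
  loc <- ev[ev$type == "local_extinction" & ev$time > half, ]
  key <- paste(loc$species_id, loc$time)
  death_regions <- loc$region[key %in% paste(dead$species_id, dead$time)]
  temperate <- sum(death_regions >= 8)
  tropical <- sum(death_regions <= 3)
  expect_gt(temperate, tropical)
})
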