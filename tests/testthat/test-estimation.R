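toy_trajectory <- function(vals) {
  tr <- data.frame(time_h = c(0, 2, 4, 6),
                   gly = vals[1:4], ser = vals[5:8], hp = vals[9:12])
  tr
}

test_that("objective error is zero at equality and exact for a uniform relative offset", {
  tr <- toy_trajectory(seq(1, 12))
  obs <- data.frame(state = rep(c("gly", "ser", "hp"), each = 4),
                    time_h = rep(c(0, 2, 4, 6), 3),
                    mean = seq(1, 12))
  expect_equal(objective_error(tr, obs), 0)
  obs2 <- obs; obs2$mean <- obs2$mean / 1.001
  expect_equal(objective_error(tr, obs2), 0.1, tolerance = 1e-6)
})

test_that("objective error equals a hand-computed table average and ignores row order", {
  tr <- toy_trajectory(c(2, 4, 6, 8,  1, 1, 2, 3,  10, 9, 8, 7))
  obs <- data.frame(state = rep(c("gly", "ser", "hp"), each = 4),
                    time_h = rep(c(0, 2, 4, 6), 3),
                    mean = c(2.2, 4, 5.4, 8.8, 0.9, 1.1, 2, 3, 10, 10, 8, 6.3))
  sim <- c(2, 4, 6, 8, 1, 1, 2, 3, 10, 9, 8, 7)
  by_hand <- 100 * mean(abs(sim - obs$mean) / pmax(obs$mean, 1e-3))
  expect_equal(objective_error(tr, obs), by_hand)
  perm <- obs[sample(nrow(obs)), ]
  expect_equal(objective_error(tr, perm), by_hand)
})

test_that("near-zero means are floored by eps and missing pairs are an error", {
  tr <- toy_trajectory(rep(c(1e-5, 1, 2), each = 4))
  obs <- data.frame(state = "gly", time_h = 0, mean = 0)
  expect_equal(objective_error(tr, obs), 100 * 1e-5 / 1e-3)
  expect_error(objective_error(tr, data.frame(state = "gly", time_h = 3, mean = 1)),
               "validation error")
  expect_error(objective_error(tr, data.frame(state = "mf", time_h = 0, mean = 1)),
               "validation error")
})

test_that("point bounds return that point with its objective, deterministically", {
  obs <- fx_obs_cv0()
  drv <- fx_col0_sim()$drivers
  truth <- unclass(fx_col0_spec()$params)
  b <- default_bounds()
  b$lower <- truth[b$parameter]; b$upper <- truth[b$parameter]
  fit <- fit_parameters(obs, drv, b, seed = 1)
  expect_equal(unclass(fit$params), truth)
  tr <- suppressWarnings(simulate_model(fx_col0_spec()$params, drv,
                                        dielCN:::.initial_state_from_obs(obs),
                                        t_grid = sort(unique(obs$time_h)),
                                        atol = 1e-8))
  expect_equal(fit$objective, objective_error(tr, obs))
})

test_that("the same seed gives an identical fit, different seeds need not", {
  obs <- fx_obs_cv05()
  drv <- fx_col0_sim()$drivers
  ctl <- pso_control(swarm_size = 8, iterations = 5)
  f1 <- fit_parameters(obs, drv, seed = 33, control = ctl)
  f2 <- fit_parameters(obs, drv, seed = 33, control = ctl)
  expect_identical(unclass(f1$params), unclass(f2$params))
  expect_identical(f1$objective, f2$objective)
})

test_that("a noise-free self-consistency run recovers the generating trajectory", {
  obs <- fx_obs_cv0()
  drv <- fx_col0_sim()$drivers
  free <- c("alpha", "f_gs_night", "km_hpr", "k_aa2bmexp", "vmax_gdc", "s_day")
  fit <- fit_parameters(obs, drv, fx_subset_bounds(free), seed = 5,
                        control = pso_control(swarm_size = 24, iterations = 60))
  expect_lt(fit$objective, 0.1)
})

test_that("tightening the box around the truth does not worsen the best objective", {
  obs <- fx_obs_cv0()
  drv <- fx_col0_sim()$drivers
  truth <- fx_col0_spec()$params
  free <- c("alpha", "f_gs_night", "km_hpr", "k_aa2bmexp")
  best_in <- function(spread) {
    b <- default_bounds(truth, spread = spread)
    pin <- !(b$parameter %in% free)
    b$lower[pin] <- unclass(truth)[b$parameter[pin]]
    b$upper[pin] <- unclass(truth)[b$parameter[pin]]
    min(vapply(1:2, function(s) {
      fit_parameters(obs, drv, b, seed = s,
                     control = pso_control(swarm_size = 16, iterations = 25))$objective
    }, 0))
  }
  wide <- best_in(0.5); narrow <- best_in(0.15)
  expect_lte(narrow, wide + 1e-8)
})

test_that("ensembles have one fit per run and an arithmetic mean trajectory", {
  obs <- fx_obs_cv05()
  drv <- fx_col0_sim()$drivers
  ens <- run_ensemble(obs, drv, n_runs = 3, base_seed = 2,
                      control = pso_control(swarm_size = 6, iterations = 4))
  expect_length(ens$fits, 3)
  manual <- Reduce(`+`, lapply(ens$fits, function(f) as.matrix(f$trajectory[, -1]))) / 3
  expect_equal(as.matrix(ens$mean_trajectory[, -1]), manual,
               ignore_attr = TRUE)
  one <- run_ensemble(obs, drv, n_runs = 1, base_seed = 2,
                      control = pso_control(swarm_size = 6, iterations = 4))
  expect_equal(as.matrix(one$mean_trajectory[, -1]),
               as.matrix(one$fits[[1]]$trajectory[, -1]), ignore_attr = TRUE)
  pars <- ensemble_parameters(ens)
  expect_equal(nrow(pars), 3)
  expect_true(all(param_names() %in% names(pars)))
})

test_that("a fit marked accepted lies within the SD band everywhere", {
  ens <- fx_recovery_ensemble()
  obs <- fx_obs_cv05()
  for (f in ens$fits) {
    rows <- match(obs$time_h, f$trajectory$time_h)
    sim <- vapply(seq_len(nrow(obs)), function(i) f$trajectory[[obs$state[i]]][rows[i]], 0)
    within <- all(abs(sim - obs$mean) <= obs$sd)
    expect_identical(f$accepted, within)
  }
})

test_that("identifiable parameters are recovered within 30% in the ensemble median", {
  ens <- fx_recovery_ensemble()
  truth <- unclass(fx_col0_spec()$params)
  pars <- ensemble_parameters(ens)
  for (p in c("alpha", "f_gs_night", "k_aa2bmexp", "km_hpr")) {
    med <- stats::median(pars[[p]])
    expect_lt(abs(med - truth[[p]]) / truth[[p]], 0.30)
  }
})

test_that("the fitted objective does not exceed the truth-evaluated objective at convergence", {
  obs <- fx_obs_cv05()
  drv <- fx_col0_sim()$drivers
  free <- c("alpha", "f_gs_night", "km_hpr", "k_aa2bmexp", "vmax_gdc", "s_day")
  fits <- lapply(1:3, function(s) {
    fit_parameters(obs, drv, fx_subset_bounds(free), seed = 100 + s,
                   control = pso_control(swarm_size = 24, iterations = 50))
  })
  y0 <- dielCN:::.initial_state_from_obs(obs)
  tr <- suppressWarnings(simulate_model(fx_col0_spec()$params, drv, y0,
                                        t_grid = sort(unique(obs$time_h)), atol = 1e-8))
  truth_obj <- objective_error(tr, obs)
  expect_lte(min(vapply(fits, function(f) f$objective, 0)), truth_obj)
})

test_that("the mutant Km bound is the ensemble minimum, optionally relaxed by 30%", {
  fake <- structure(list(fits = lapply(c(2, 3, 4), function(k) {
    list(params = kinetic_params(km_hpr = k))
  })), class = "cn_ensemble")
  expect_equal(hpr_km_bound(fake), 2)
  expect_equal(hpr_km_bound(fake, relax = TRUE), 1.4)
  empty <- structure(list(fits = list()), class = "cn_ensemble")
  expect_error(hpr_km_bound(empty), "empty ensemble")
})
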