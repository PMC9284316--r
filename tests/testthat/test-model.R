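test_that("flux vector matches an independently hand-coded rate-law table", {
  spec <- fx_col0_spec()
  drv <- fx_col0_sim()$drivers
  set.seed(1)
  for (i in 1:25) {
    p <- random_params()
    st <- random_healthy_state()
    t <- runif(1, 0, 24)
    v <- evaluate_fluxes(st, t, p, drv)
    o <- oracle_fluxes(unclass(st), t, unclass(p), drv)
    # depletion gates deviate by <= gate_eps/pool from the exact table
    expect_equal(v[names(o)], o, tolerance = 1e-3)
  }
})

test_that("half-saturation propagates through the GDC flux", {
  spec <- fx_col0_spec()
  st <- unclass(fx_col0_spec()$y0)
  p <- unclass(spec$params)
  st["gly"] <- p[["km_gdc"]] * 0.77
  v <- evaluate_fluxes(metabolite_state(st), 2, spec$params, fx_col0_sim()$drivers)
  expect_equal(unname(v["v_gdc"]), p[["vmax_gdc"]] / 2)
})

test_that("with all mass-balance constants and alpha zero, only enzymatic and boundary fluxes survive in the dark", {
  spec <- fx_col0_spec()
  p <- unclass(spec$params)
  p[c("k_hp2bmexp", "k_hp2mf", "k_mf2cit", "k_cit2mf", "k_cit2kg",
      "k_ser2aa", "k_aa2bmexp", "alpha")] <- 0
  v <- evaluate_fluxes(fx_col0_spec()$y0, 12, kinetic_params(values = p),
                       fx_col0_sim()$drivers)
  # v_glu2aa rides on NR (correct * v_nr), so it stays active with NR
  maybe_nonzero <- c("v_starch", "v_resp", "v_nr", "v_gs", "v_gogat",
                     "v_gdc", "v_shmt", "v_hpr", "v_ps_in", "v_glu2aa")
  expect_true(all(abs(v[setdiff(names(v), maybe_nonzero)]) < 1e-12))
})

test_that("derived-flux identities hold: SHMT cap, N1 balance, correct factor, Ser-to-biomass share", {
  drv <- fx_col0_sim()$drivers
  set.seed(2)
  for (i in 1:25) {
    p <- random_params(); st <- random_healthy_state(); t <- runif(1, 0, 24)
    v <- evaluate_fluxes(st, t, p, drv)
    expect_lte(v[["v_shmt"]], v[["v_gdc"]] + 1e-12)
    expect_equal(v[["v_glu2kg"]], max(v[["v_pr"]] - v[["v_hpr"]], 0), tolerance = 1e-3)
    expect_equal(v[["v_glu2aa"]], unclass(p)[["correct"]] * v[["v_nr"]], tolerance = 1e-3)
    expect_equal(v[["v_ser2bm"]], 0.14 * v[["v_aa2bmexp"]], tolerance = 1e-3)
    reaction <- setdiff(names(v), c("v_ps_in", "v_starch"))
    expect_true(all(v[reaction] >= 0))
  }
})

test_that("the right-hand side equals the stoichiometry matrix applied to the fluxes", {
  drv <- fx_col0_sim()$drivers
  set.seed(3)
  for (t in c(1.3, 4.0, 9.7, 17.2)) {
    p <- random_params(); st <- random_healthy_state()
    v <- evaluate_fluxes(st, t, p, drv)
    S <- oracle_stoichiometry(light = is_light(t))
    expect_equal(unclass(model_rhs(st, t, p, drv)),
                 drop(S %*% v[colnames(S)]), tolerance = 1e-12)
  }
})

test_that("a lone GS flux moves one N from Glu and one from NH4 into Gln", {
  S <- oracle_stoichiometry(TRUE)
  col <- S[, "v_gs"]
  expect_equal(col[c("gln", "glu", "nh4")], c(gln = 1, glu = -1, nh4 = -1))
  expect_true(all(col[setdiff(names(col), c("gln", "glu", "nh4"))] == 0))
})

test_that("nitrogen and carbon balances close to 1e-8 of the largest flux", {
  drv <- fx_col0_sim()$drivers
  set.seed(4)
  for (i in 1:30) {
    p <- random_params(); st <- random_healthy_state(); t <- runif(1, 0, 24)
    v <- evaluate_fluxes(st, t, p, drv)
    d <- model_rhs(st, t, p, drv)
    tol <- 1e-8 * max(abs(v))
    expect_lt(abs(sum(oracle_n_weights * d) - oracle_n_balance(v)), tol)
    expect_lt(abs(sum(oracle_c_weights * d) - oracle_c_balance(v, is_light(t))), tol)
  }
})

test_that("with alpha = 0 the photorespiratory flux vanishes throughout the dark phase", {
  spec <- fx_col0_spec()
  p <- kinetic_params(values = `[<-`(unclass(spec$params), "alpha", 0))
  drv <- fx_col0_sim()$drivers
  for (t in seq(8, 23.5, by = 0.5)) {
    v <- evaluate_fluxes(spec$y0, t, p, drv)
    expect_identical(unname(v["v_pr"]), 0)
  }
})

test_that("zero state and zero drivers give a zero derivative", {
  p <- unclass(default_params())
  p[grep("^(vmax|k_|s_day|alpha)", names(p))] <- 0
  zero_gx <- data.frame(time_h = seq(0, 7.5, 0.5), flux = 0)
  zact <- data.frame(time_h = c(0, 4, 8, 16), vmax = 0)
  drv0 <- driver_set(build_ps_spline(zero_gx, rd = 0), rd = 0,
                     vmax_nr = build_vmax_spline(zact),
                     vmax_gs = build_vmax_spline(zact),
                     vmax_hpr = build_vmax_spline(zact),
                     co2 = 450, gamma_star = 45, no3_total = 0)
  st0 <- metabolite_state(stats::setNames(rep(0, 10), dielCN:::state_names()))
  expect_true(all(model_rhs(st0, 3, kinetic_params(values = p), drv0) == 0))
  tr <- simulate_model(kinetic_params(values = p), drv0,
                       fx_col0_spec()$y0, t_grid = seq(0, 24, 4))
  for (s in dielCN:::state_names()) {
    expect_equal(tr[[s]], rep(fx_col0_spec()$y0[[s]], nrow(tr)), tolerance = 1e-7)
  }
})

test_that("a lone first-order drain gives exponential decay", {
  p <- unclass(default_params())
  p[grep("^(vmax|k_|s_day|alpha)", names(p))] <- 0
  p["k_ser2aa"] <- 0.4
  zero_gx <- data.frame(time_h = seq(0, 7.5, 0.5), flux = 0)
  zact <- data.frame(time_h = c(0, 4, 8, 16), vmax = 0)
  drv0 <- driver_set(build_ps_spline(zero_gx, rd = 0), rd = 0,
                     vmax_nr = build_vmax_spline(zact),
                     vmax_gs = build_vmax_spline(zact),
                     vmax_hpr = build_vmax_spline(zact),
                     co2 = 450, gamma_star = 45, no3_total = 0)
  y0 <- fx_col0_spec()$y0
  tr <- simulate_model(kinetic_params(values = p), drv0, y0, t_grid = 0:10)
  expect_equal(tr$ser, y0[["ser"]] * exp(-0.4 * (0:10)), tolerance = 1e-5)
  expect_equal(tr$aa, y0[["aa"]] + y0[["ser"]] * (1 - exp(-0.4 * (0:10))),
               tolerance = 1e-5)
})

test_that("adaptive integration agrees with a fixed-step RK4 oracle to 0.1% per state", {
  cmp <- fx_rk4_comparison()
  for (s in dielCN:::state_names()) {
    scale <- max(abs(cmp$rk4[[s]]))
    expect_lt(max(abs(cmp$lsoda[[s]] - cmp$rk4[[s]])) / scale, 1e-3)
  }
})

test_that("compiled and interpreted engines agree", {
  spec <- fx_col0_spec(); drv <- fx_col0_sim()$drivers
  # the exact light-off instant is excluded: the trajectory is continuous
  # there but pools in free fall make the point value ill-conditioned
  grid <- c(seq(0, 6, by = 2), seq(10, 22, by = 2))
  a <- simulate_model(spec$params, drv, spec$y0, t_grid = grid)
  b <- simulate_model(spec$params, drv, spec$y0, t_grid = grid, engine = "R")
  for (s in dielCN:::state_names()) {
    scale <- max(abs(b[[s]]))
    expect_lt(max(abs(a[[s]] - b[[s]])) / scale, 2e-3)
  }
})

test_that("trajectories respond continuously to small parameter perturbations", {
  spec <- fx_col0_spec(); drv <- fx_col0_sim()$drivers
  p1 <- unclass(spec$params)
  p1["f_gs_night"] <- 1
  p2 <- p1 * (1 + 1e-7)
  p2["correct"] <- min(p2[["correct"]], 1); p2["f_gs_night"] <- 1
  a <- simulate_model(kinetic_params(values = p1), drv, spec$y0, seq(0, 24, 2))
  b <- simulate_model(kinetic_params(values = p2), drv, spec$y0, seq(0, 24, 2))
  expect_lt(max(abs(as.matrix(a[, -1]) - as.matrix(b[, -1]))), 1e-3)
})

test_that("simulation validates its inputs", {
  spec <- fx_col0_spec(); drv <- fx_col0_sim()$drivers
  expect_error(simulate_model(spec$params, drv, spec$y0, t_grid = c(2, 4)),
               "t_grid")
  expect_error(simulate_model(spec$params, drv, spec$y0, t_grid = c(0, 30)),
               "t_grid")
  bad <- unclass(spec$y0); bad["gly"] <- -1
  expect_error(simulate_model(spec$params, drv, bad, t_grid = 0:2), ">= 0")
})

test_that("tidy exports carry the full trajectory and flux tables", {
  sim <- fx_col0_sim()
  td <- tidy_trajectory(sim$trajectory, condition = "Col-0_ambient", run_id = 3L)
  expect_named(td, c("condition", "run_id", "time_h", "state", "value_umol_per_gFW"))
  expect_equal(nrow(td), nrow(sim$trajectory) * 10)
  fl <- trajectory_fluxes(sim$trajectory, fx_col0_spec()$params, sim$drivers)
  tf <- tidy_fluxes(fl, condition = "Col-0_ambient")
  expect_named(tf, c("condition", "run_id", "time_h", "flux", "value_umol_per_gFW_per_h"))
  expect_equal(nrow(tf), nrow(fl) * 20)
})
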