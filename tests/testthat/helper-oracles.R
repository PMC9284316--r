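# Independent oracles: a second, structurally different implementation of the
# rate-law table, the stoichiometry, the element balances, and a fixed-step
# RK4 integrator. These deliberately do not call the package internals they
# check.

oracle_fluxes <- function(state, t, p, drv) {
  vol <- 0.77
  conc <- function(x) max(x, 0) / vol
  mm <- function(s, vmax, km) vmax * s / (km + s)
  light <- (t %% 24) < drv$light_hours

  a_net <- drv$ps(t)
  phi <- 2 * drv$gamma_star / drv$co2
  v_o <- if (light && phi > 0) max((a_net + drv$rd) / (1 / phi - 0.5), 0) else 0
  out <- c(
    v_pr = unname((if (light) v_o / 2 else 0) + p["alpha"]),
    v_gdc = mm(conc(state["gly"]), p[["vmax_gdc"]], p[["km_gdc"]]),
    v_hpr = mm(conc(state["ser"]), drv$vmax_hpr(t), p[["km_hpr"]]),
    v_nr = mm(0.05 * drv$no3_total / vol, drv$vmax_nr(t), p[["km_nr"]]),
    v_gogat = p[["vmax_gogat"]] *
      conc(state["gln"]) / (p[["km_gogat_gln"]] + conc(state["gln"])) *
      conc(state["kg"]) / (p[["km_gogat_kg"]] + conc(state["kg"])),
    v_hp2bmexp = p[["k_hp2bmexp"]] * max(state[["hp"]], 0),
    v_hp2mf = p[["k_hp2mf"]] * max(state[["hp"]], 0),
    v_mf2cit = if (drv$gate_carboxylates && light) 0 else p[["k_mf2cit"]] * max(state[["mf"]], 0),
    v_cit2mf = p[["k_cit2mf"]] * max(state[["cit"]], 0),
    v_cit2kg = if (drv$gate_carboxylates && !light) 0 else p[["k_cit2kg"]] * max(state[["cit"]], 0),
    v_ser2aa = p[["k_ser2aa"]] * max(state[["ser"]], 0),
    v_aa2bmexp = p[["k_aa2bmexp"]] * max(state[["aa"]], 0),
    v_resp = drv$rd / 4,
    v_starch = if (light) p[["s_day"]] else p[["s_day"]] * drv$light_hours / (24 - drv$light_hours)
  )
  out["v_shmt"] <- min(mm(conc(state["gly"]), p[["vmax_shmt"]], p[["km_shmt"]]),
                       out["v_gdc"])
  out["v_gs"] <- drv$vmax_gs(t) * (if (light) 1 else p[["f_gs_night"]]) *
    conc(state["nh4"]) / (p[["km_gs_nh4"]] + conc(state["nh4"])) *
    conc(state["glu"]) / (p[["km_gs_glu"]] + conc(state["glu"]))
  out["v_glu2kg"] <- max(out[["v_pr"]] - out[["v_hpr"]], 0)
  out["v_glu2aa"] <- p[["correct"]] * out[["v_nr"]]
  out["v_ser2bm"] <- 0.14 * out[["v_aa2bmexp"]]
  out["v_ps_in"] <- (a_net + drv$rd + out[["v_gdc"]] - 2 * out[["v_pr"]]) / 6
  out
}

# Stoichiometry matrix: rows = states, columns = fluxes; the starch column is
# phase-dependent (HP -> starch by day, starch -> HP by night).
oracle_stoichiometry <- function(light) {
  st <- c("gly", "ser", "hp", "mf", "cit", "kg", "glu", "gln", "aa", "nh4")
  fl <- c("v_ps_in", "v_starch", "v_pr", "v_gdc", "v_shmt", "v_hpr",
          "v_ser2aa", "v_ser2bm", "v_glu2kg", "v_gs", "v_gogat", "v_nr",
          "v_glu2aa", "v_aa2bmexp", "v_hp2bmexp", "v_hp2mf",
          "v_mf2cit", "v_cit2mf", "v_cit2kg", "v_resp")
  S <- matrix(0, length(st), length(fl), dimnames = list(st, fl))
  S["hp", "v_ps_in"] <- 1
  S["hp", "v_starch"] <- if (light) -1 else 1
  S["gly", "v_pr"] <- 1
  S["gly", "v_gdc"] <- -1; S["nh4", "v_gdc"] <- 1
  S["gly", "v_shmt"] <- -1; S["ser", "v_shmt"] <- 1
  S["ser", "v_hpr"] <- -1; S["hp", "v_hpr"] <- 0.5
  S["ser", "v_ser2aa"] <- -1; S["aa", "v_ser2aa"] <- 1
  S["ser", "v_ser2bm"] <- -1
  S["glu", "v_glu2kg"] <- -1; S["kg", "v_glu2kg"] <- 1
  S["glu", "v_gs"] <- -1; S["nh4", "v_gs"] <- -1; S["gln", "v_gs"] <- 1
  S["gln", "v_gogat"] <- -1; S["kg", "v_gogat"] <- -1; S["glu", "v_gogat"] <- 2
  S["nh4", "v_nr"] <- 1
  S["glu", "v_glu2aa"] <- -1; S["aa", "v_glu2aa"] <- 1
  S["aa", "v_aa2bmexp"] <- -1
  S["hp", "v_hp2bmexp"] <- -1
  S["hp", "v_hp2mf"] <- -1; S["mf", "v_hp2mf"] <- 1.5
  S["mf", "v_mf2cit"] <- -1.5; S["cit", "v_mf2cit"] <- 1
  S["cit", "v_cit2mf"] <- -1; S["mf", "v_cit2mf"] <- 1.5
  S["cit", "v_cit2kg"] <- -1; S["kg", "v_cit2kg"] <- 1.2
  S["mf", "v_resp"] <- -1
  S
}

# Analytic element balances assembled term by term from a flux vector.
oracle_n_balance <- function(v) {
  v[["v_pr"]] + v[["v_nr"]] - v[["v_hpr"]] - v[["v_glu2kg"]] -
    v[["v_ser2bm"]] - v[["v_aa2bmexp"]]
}

oracle_c_balance <- function(v, light) {
  6 * v[["v_ps_in"]] + (if (light) -6 else 6) * v[["v_starch"]] +
    2 * v[["v_pr"]] - 2 * v[["v_gdc"]] + v[["v_shmt"]] -
    3 * v[["v_ser2aa"]] - 3 * v[["v_ser2bm"]] - 5 * v[["v_glu2aa"]] -
    6 * v[["v_hp2bmexp"]] - 4 * v[["v_resp"]]
}

# Carbon weights per pool (aa is tracked in N units and excluded; nh4 has no C).
oracle_c_weights <- c(gly = 2, ser = 3, hp = 6, mf = 4, cit = 6, kg = 5,
                      glu = 5, gln = 5, aa = 0, nh4 = 0)
oracle_n_weights <- c(gly = 1, ser = 1, hp = 0, mf = 0, cit = 0, kg = 0,
                      glu = 1, gln = 2, aa = 1, nh4 = 1)

# Fixed-step classic RK4 on the package's interpreted right-hand side.
oracle_rk4 <- function(params, drivers, y0, t_grid, h = 0.005) {
  y <- as.numeric(y0[dielCN:::state_names()])
  out <- matrix(NA_real_, length(t_grid), 10)
  out[1, ] <- y
  tcur <- t_grid[1]
  f <- function(t, y) as.numeric(model_rhs(stats::setNames(pmax(y, 0), dielCN:::state_names()),
                                           min(t, 24 - 1e-9), params, drivers))
  for (i in seq_along(t_grid)[-1]) {
    target <- t_grid[i]
    while (tcur < target - 1e-12) {
      step <- min(h, target - tcur)
      # do not step across the light/dark switch
      lh <- drivers$light_hours
      if (tcur < lh && tcur + step > lh) step <- lh - tcur
      k1 <- f(tcur, y)
      k2 <- f(tcur + step / 2, y + step / 2 * k1)
      k3 <- f(tcur + step / 2, y + step / 2 * k2)
      k4 <- f(tcur + step, y + step * k3)
      y <- pmax(y + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
      tcur <- tcur + step
    }
    out[i, ] <- y
  }
  colnames(out) <- dielCN:::state_names()
  data.frame(time_h = t_grid, out)
}

random_healthy_state <- function() {
  metabolite_state(stats::setNames(stats::runif(10, 0.5, 15), dielCN:::state_names()))
}

random_params <- function(jitter = 0.3) {
  p <- unclass(default_params())
  p <- p * stats::runif(length(p), 1 - jitter, 1 + jitter)
  p["correct"] <- min(max(p["correct"], 0.5), 1)
  p["f_gs_night"] <- min(max(p["f_gs_night"], 0.05), 1)
  kinetic_params(values = p)
}
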