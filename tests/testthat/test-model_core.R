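timing80 <- c(heart_rate = 80, t_sas = 0.2, t_svs = 0.4, t_pws = 9.5)

test_that("activation windows follow the half-cosine form", {
  t_c <- 60 / 80; t_sv <- t_c * 0.4
  # symmetry midpoint of the ventricular window reaches full activation
  expect_equal(activation(t_sv / 2, timing80)$A_v, 1)
  # zero at window start and outside the window
  expect_equal(activation(0, timing80)$A_v, 0)
  expect_equal(activation(t_sv, timing80)$A_v, 0)
  expect_equal(activation(t_sv + 0.05, timing80)$A_v, 0)
  # HR = 80 gives a 0.75 s cycle and the window ends at 0.30 s
  expect_gt(activation(0.299, timing80)$A_v, 0)
  expect_equal(activation(0.301, timing80)$A_v, 0)
  # quarter window evaluates the cosine directly
  expect_equal(activation(t_sv / 4, timing80)$A_v,
               0.5 * (1 - cos(pi / 2)))
})

test_that("activation stays in [0, 1] over random times and timings", {
  set.seed(42)
  n <- 1e6
  hr <- runif(n, 30, 200)
  tim <- cbind(heart_rate = hr, t_sas = runif(n, 0.01, 0.99),
               t_svs = runif(n, 0.01, 0.99), t_pws = runif(n, 1.01, 30))
  tt <- runif(n, 0, 10)
  # spot-check distinct random timings, aggregated into one assertion
  idx <- sample.int(n, 2000)
  ok <- vapply(idx, function(i) {
    a <- activation(tt[i], tim[i, ])
    a$A_a >= 0 && a$A_a <= 1 && a$A_v >= 0 && a$A_v <= 1
  }, logical(1))
  expect_true(all(ok))
  # plus one large fully vectorised sweep at a fixed timing
  a <- activation(runif(n, 0, 100), timing80)
  expect_true(all(a$A_a >= 0 & a$A_a <= 1))
  expect_true(all(a$A_v >= 0 & a$A_v <= 1))
})

test_that("invalid timing is rejected", {
  expect_error(activation(0.1, c(heart_rate = -1, t_sas = 0.2,
                                 t_svs = 0.4, t_pws = 9.5)), "heart_rate")
  expect_error(activation(0.1, c(heart_rate = 80, t_sas = 1.2,
                                 t_svs = 0.4, t_pws = 9.5)), "t_sas")
  expect_error(activation(0.1, c(heart_rate = 80, t_sas = 0.2,
                                 t_svs = 0.4, t_pws = 0.5)), "t_pws")
})

test_that("chamber pressure combines passive and active terms", {
  cp <- c(E_act = 2, K_pas1 = 1, K_pas2 = 0.01, V0 = 10)
  # both terms vanish at the unstressed volume
  expect_equal(chamber_pressure(10, 0.7, cp), 0)
  # diastolic limit: activation zero leaves the passive curve only
  expect_equal(chamber_pressure(110, 0, cp), exp(1) - 1)
  # direct evaluation with both terms
  expect_equal(chamber_pressure(110, 1, cp), (exp(1) - 1) + 200)
  # exponential overflow raises a divergence error
  expect_error(chamber_pressure(1e6, 0, cp), "diverged")
})

test_that("valve momentum equation handles open/closed states", {
  # closed valve carries no momentum
  expect_equal(valve_flow_rhs(5, 10, 20, R = 1, L = 1), 0)
  # steady flow: pressure gradient balances resistive loss
  expect_equal(valve_flow_rhs(10, 100, 90, R = 1, L = 1), 0)
  # unit case
  expect_equal(valve_flow_rhs(0, 3, 2, R = 1, L = 1), 1)
  expect_error(valve_flow_rhs(0, 1, 0, R = -1, L = 1), "R and L")
})

test_that("the loop is closed: total stressed volume is conserved by the RHS", {
  p <- default_parameters("healthy")
  set.seed(1)
  ok <- vapply(1:25, function(k) {
    x <- c(runif(4, 20, 200), runif(4, 0, 300),
           runif(3, c(0.5, 0.05, 0.05) * 1e5, c(2, 0.5, 0.5) * 1e5))
    names(x) <- state_names()
    d <- system_rhs(runif(1, 0, 0.75), x, p)
    dtot <- sum(d[1:4]) + p[["C_ao"]] * d[["P_ao"]] +
      p[["C_sys"]] * d[["P_sys"]] + p[["C_pa"]] * d[["P_pa"]]
    abs(dtot) < 1e-9 * max(abs(d))
  }, logical(1))
  expect_true(all(ok))
})

test_that("R reference RHS matches the compiled RHS", {
  p <- default_parameters("healthy")
  set.seed(2)
  for (k in 1:20) {
    x <- c(runif(4, 20, 200), runif(4, 0, 300),
           runif(3, 0.05e5, 2e5))
    names(x) <- state_names()
    t <- runif(1, 0, 1.5)
    expect_equal(unname(system_rhs(t, x, p)),
                 as.vector(cardiolpn:::.lpn_rhs(t, unname(x), unname(p))),
                 tolerance = 1e-12)
  }
})

test_that("matched node pressures and zero valve flows still the volumes", {
  p <- default_parameters("healthy")
  t <- 0.44  # late diastole for this anchor
  act <- activation(t, p[c("heart_rate", "t_sas", "t_svs", "t_pws")])
  x <- c(V_ra = 50, V_rv = 100, V_la = 50, V_lv = 100,
         Q_ra_rv = 0, Q_rv_pa = 0, Q_la_lv = 0, Q_lv_ao = 0,
         P_ao = 1e5, P_sys = 1e5, P_pa = 1e5)
  # equal pulmonary and left-atrial pressures zero the pulmonary flux
  x["P_pa"] <- chamber_pressure(50, act$A_a,
                                cardiolpn:::chamber_par(p, "la"))
  d <- system_rhs(t, x, p)
  expect_equal(unname(d[["V_la"]]), 0)   # Q_pa = 0 and no mitral flow
  expect_equal(unname(d[["V_rv"]]), 0)   # both valve flows are zero
  expect_equal(unname(d[["V_lv"]]), 0)
})

test_that("simulation reaches a periodic steady state with conserved volume", {
  w <- healthy_waveforms()
  expect_true(w$converged)
  expect_equal(w$t_c, 60 / w$params[["heart_rate"]])
  expect_equal(max(w$time), w$t_c, tolerance = 1e-10)
  p <- w$params
  tot <- w$V_ra + w$V_rv + w$V_la + w$V_lv +
    p[["C_ao"]] * w$P_ao + p[["C_sys"]] * w$P_sys + p[["C_pa"]] * w$P_pa
  # total stressed volume constant over the cycle (well under 0.1%)
  expect_lt(diff(range(tot)) / mean(tot), 1e-3)
  # conserved from the initial conditions through the whole integration
  tot0 <- sum(p[c("V_ra_ini", "V_rv_ini", "V_la_ini", "V_lv_ini")]) +
    p[["C_ao"]] * p[["P_ao_ini"]] + p[["C_sys"]] * p[["P_sys_ini"]] +
    p[["C_pa"]] * p[["P_pa_ini"]]
  expect_lt(abs(mean(tot) - tot0) / tot0, 1e-3)
})

test_that("valves are one-way and flow balances at periodicity", {
  w <- healthy_waveforms()
  expect_true(all(w$Q_ra_rv >= 0 & w$Q_rv_pa >= 0 &
                    w$Q_la_lv >= 0 & w$Q_lv_ao >= 0))
  expect_true(all(w$phi_T %in% 0:1 & w$phi_P %in% 0:1 &
                    w$phi_M %in% 0:1 & w$phi_A %in% 0:1))
  n <- length(w$time) - 1
  # flow conservation at periodicity, using the continuous fluxes (the
  # sampled valve flows carry O(dt) jumps at the closure discontinuities)
  m_sys <- mean(w$Q_sys_a[1:n])
  m_pa <- mean(w$Q_pa[1:n])
  expect_lt(abs(m_sys - m_pa) / m_pa, 0.005)
  sv_rate <- (max(w$V_lv) - min(w$V_lv)) / w$t_c
  expect_lt(abs(sv_rate - m_pa) / m_pa, 0.01)
})

test_that("halving the integrator step leaves waveform extrema unchanged", {
  p <- default_parameters("healthy")
  w1 <- suppressWarnings(
    simulate_model(p, sim_config(steps_per_cycle = 1000, max_cycles = 80)))
  w2 <- suppressWarnings(
    simulate_model(p, sim_config(steps_per_cycle = 2000, max_cycles = 80)))
  for (q in c("P_ao", "P_pa", "P_lv", "V_lv")) {
    expect_lt(abs(max(w1[[q]]) - max(w2[[q]])) / abs(max(w2[[q]])), 0.005)
    den <- max(abs(min(w2[[q]])), 0.01 * max(abs(w2[[q]])))
    expect_lt(abs(min(w1[[q]]) - min(w2[[q]])) / den, 0.005)
  }
})

test_that("stiffer passive LV raises left atrial pressure (diastolic mechanism)", {
  p <- default_parameters("healthy")
  mpla <- vapply(c(1, 1.5, 2.25), function(f) {
    q <- p; q[["K_pas1_lv"]] <- p[["K_pas1_lv"]] * f
    w <- simulate_model(q)
    mean(w$P_la[1:(length(w$time) - 1)])
  }, numeric(1))
  expect_true(all(diff(mpla) >= 0))
})

test_that("divergence is reported with the offending parameters attached", {
  p <- default_parameters("healthy")
  p[["K_pas2_lv"]] <- 0.119  # extreme stiffness exponent blows up
  p[["V_lv_ini"]] <- 299
  err <- tryCatch(simulate_model(p), cardiolpn_diverged = function(e) e,
                  warning = function(w) NULL, error = function(e) e)
  # either diverges (carrying params) or flags non-convergence
  if (inherits(err, "cardiolpn_diverged")) {
    expect_named_num(err$params)
  } else succeed()
})
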