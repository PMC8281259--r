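#' Atrial and ventricular activation functions
#'
#' Half-cosine activation windows driving the active elastance of the heart
#' chambers. The cycle starts (\code{t = 0}) at the onset of ventricular
#' systole; the ventricular window spans \code{[0, t_sv)} with
#' \code{t_sv = t_c * t_svs}, and the atrial window is shifted by the atrial
#' delay \code{t_pw = t_c / t_pws}.
#'
#' @param t Time in seconds (vectorised).
#' @param timing Named numeric vector (or list) with \code{heart_rate},
#'   \code{t_sas}, \code{t_svs}, \code{t_pws}.
#' @return A list with vectors \code{A_a} and \code{A_v}, both in [0, 1].
#' @export
activation <- function(t, timing) {
  timing <- unlist(timing)
  hr <- timing[["heart_rate"]]
  if (!is.finite(hr) || hr <= 0) stop("heart_rate must be > 0", call. = FALSE)
  t_sas <- timing[["t_sas"]]; t_svs <- timing[["t_svs"]]
  t_pws <- timing[["t_pws"]]
  if (t_sas <= 0 || t_sas >= 1 || t_svs <= 0 || t_svs >= 1)
    stop("t_sas and t_svs must lie in (0, 1)", call. = FALSE)
  if (t_pws <= 1) stop("t_pws must be > 1", call. = FALSE)
  t_c <- 60 / hr
  t_sa <- t_c * t_sas; t_sv <- t_c * t_svs; t_pw <- t_c / t_pws
  t_mv <- t %% t_c
  t_ma <- (t + t_sa - t_pw) %% t_c
  A_v <- ifelse(t_mv < t_sv, 0.5 * (1 - cos(2 * pi * t_mv / t_sv)), 0)
  A_a <- ifelse(t_ma < t_sa, 0.5 * (1 - cos(2 * pi * t_ma / t_sa)), 0)
  list(A_a = A_a, A_v = A_v)
}

#' Elastance-chamber pressure
#'
#' Pressure of a heart chamber as the sum of a passive exponential curve and
#' an activation-scaled linear active curve:
#' \code{P = K_pas1 (exp(K_pas2 (V - V0)) - 1) + A E_act (V - V0)}.
#'
#' @param V Chamber volume, mL (vectorised).
#' @param A Activation in [0, 1] (vectorised).
#' @param cp Named vector/list with \code{E_act}, \code{K_pas1},
#'   \code{K_pas2}, \code{V0}.
#' @return Pressure in Barye.
#' @export
chamber_pressure <- function(V, A, cp) {
  cp <- unlist(cp)
  arg <- cp[["K_pas2"]] * (V - cp[["V0"]])
  if (any(arg > 500))
    stop("simulation diverged: passive pressure overflow at V = ",
         max(V), " mL", call. = FALSE)
  cp[["K_pas1"]] * (exp(arg) - 1) + A * cp[["E_act"]] * (V - cp[["V0"]])
}

#' Valve flow momentum equation
#'
#' Rate of change of flow through a valve modelled as a resistance-inertance
#' pair behind a perfect one-way valve: open valves obey
#' \code{dQ/dt = (P_up - P_dn - R Q)/L}; closed valves carry no momentum and
#' the integrator resets their flow state to zero on closure.
#'
#' @param Q Current flow, mL/s.
#' @param P_up,P_dn Upstream and downstream pressures, Barye.
#' @param R Valve resistance, Barye s/mL. @param L Inertance, Barye s^2/mL.
#' @param open Logical; valve open (\code{P_up > P_dn}).
#' @return dQ/dt in mL/s^2.
#' @export
valve_flow_rhs <- function(Q, P_up, P_dn, R, L, open = P_up > P_dn) {
  if (R <= 0 || L <= 0) stop("R and L must be > 0", call. = FALSE)
  if (open) (P_up - P_dn - R * Q) / L else 0
}

#' State names of the circulation ODE system
#' @return Character vector of the 11 state names.
#' @export
state_names <- function() {
  c("V_ra", "V_rv", "V_la", "V_lv",
    "Q_ra_rv", "Q_rv_pa", "Q_la_lv", "Q_lv_ao",
    "P_ao", "P_sys", "P_pa")
}

chamber_par <- function(params, ch) {
  c(E_act = unname(params[[paste0("E_act_", ch)]]),
    K_pas1 = unname(params[[paste0("K_pas1_", ch)]]),
    K_pas2 = unname(params[[paste0("K_pas2_", ch)]]),
    V0 = unname(params[[paste0("V0_", ch)]]))
}

#' Right-hand side of the closed-loop circulation system
#'
#' Time derivatives of the 11 model states (four chamber volumes, four valve
#' flows, aortic/systemic/pulmonary capacitor pressures). The algebraic
#' fluxes through the systemic resistances and the pulmonary resistance are
#' computed internally. This reference implementation mirrors the compiled
#' integrator and is used for testing and didactic purposes.
#'
#' @param t Time, s.
#' @param state Named (or canonically ordered) numeric vector of 11 states.
#' @param params Parameter vector (see \code{\link{parameter_names}}).
#' @return Named numeric vector of 11 derivatives.
#' @export
system_rhs <- function(t, state, params) {
  p <- params[parameter_names()]
  x <- unname(state[state_names()])
  if (is.null(names(state))) x <- unname(state)
  act <- activation(t, p[c("heart_rate", "t_sas", "t_svs", "t_pws")])
  P_ra <- chamber_pressure(x[1], act$A_a, chamber_par(p, "ra"))
  P_rv <- chamber_pressure(x[2], act$A_v, chamber_par(p, "rv"))
  P_la <- chamber_pressure(x[3], act$A_a, chamber_par(p, "la"))
  P_lv <- chamber_pressure(x[4], act$A_v, chamber_par(p, "lv"))
  P_ao <- x[9]; P_sys <- x[10]; P_pa <- x[11]
  phi <- c(T = P_ra > P_rv, P = P_rv > P_pa, M = P_la > P_lv, A = P_lv > P_ao)
  QT <- x[5] * phi[["T"]]; QP <- x[6] * phi[["P"]]
  QM <- x[7] * phi[["M"]]; QA <- x[8] * phi[["A"]]
  Q_sys_a <- (P_ao - P_sys) / p[["R_sys_a"]]
  Q_sys_v <- (P_sys - P_ra) / p[["R_sys_v"]]
  Q_pa <- (P_pa - P_la) / p[["R_pa"]]
  d <- c(
    V_ra = Q_sys_v - QT,
    V_rv = QT - QP,
    V_la = Q_pa - QM,
    V_lv = QM - QA,
    Q_ra_rv = valve_flow_rhs(x[5], P_ra, P_rv, p[["R_ra_rv"]], p[["L_ra_rv"]],
                             phi[["T"]]),
    Q_rv_pa = valve_flow_rhs(x[6], P_rv, P_pa, p[["R_rv_pa"]], p[["L_rv_pa"]],
                             phi[["P"]]),
    Q_la_lv = valve_flow_rhs(x[7], P_la, P_lv, p[["R_la_lv"]], p[["L_la_lv"]],
                             phi[["M"]]),
    Q_lv_ao = valve_flow_rhs(x[8], P_lv, P_ao, p[["R_lv_ao"]], p[["L_lv_ao"]],
                             phi[["A"]]),
    P_ao = (QA - Q_sys_a) / p[["C_ao"]],
    P_sys = (Q_sys_a - Q_sys_v) / p[["C_sys"]],
    P_pa = (QP - Q_pa) / p[["C_pa"]])
  if (any(!is.finite(d)))
    stop("simulation diverged: non-finite derivative", call. = FALSE)
  d
}

#' Simulation configuration
#'
#' @param steps_per_cycle RK4 steps per cardiac cycle (>= 200).
#' @param max_cycles Maximum number of cycles integrated (>= 2).
#' @param periodicity_tol Relative tolerance on cycle-to-cycle change of
#'   every state's cycle mean.
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(steps_per_cycle = 1000, max_cycles = 50,
                       periodicity_tol = 1e-4) {
  stopifnot(steps_per_cycle >= 200, max_cycles >= 2, periodicity_tol > 0)
  structure(list(steps_per_cycle = as.integer(steps_per_cycle),
                 max_cycles = as.integer(max_cycles),
                 periodicity_tol = periodicity_tol),
            class = "sim_config")
}

#' Simulate the circulation model to a periodic steady state
#'
#' Integrates the closed-loop system with a fixed-step fourth-order
#' Runge-Kutta scheme from the initial conditions carried in \code{params},
#' cycle by cycle, until the relative change of every state's cycle mean
#' falls below \code{periodicity_tol} or \code{max_cycles} is reached.
#' Returns the final cycle with all derived waveforms.
#'
#' @param params Named 45-parameter vector.
#' @param config A \code{\link{sim_config}}.
#' @return An object of class \code{"circ_waveforms"}: a list with
#'   \code{time} (s, one cycle), pressure/volume/flow waveforms (Barye, mL,
#'   mL/s), valve indicators \code{phi_T/P/M/A}, activations, and flags
#'   \code{converged}, \code{cycles}.
#' @export
simulate_model <- function(params, config = sim_config()) {
  p <- validate_parameters(params)
  res <- .lpn_simulate(unname(p), config$steps_per_cycle, config$max_cycles,
                       config$periodicity_tol)
  if (isTRUE(res$diverged)) {
    cond <- structure(
      class = c("cardiolpn_diverged", "error", "condition"),
      list(message = "simulation diverged (non-finite or non-physical state)",
           call = sys.call(-1), params = p))
    stop(cond)
  }
  st <- res$states
  colnames(st) <- state_names()
  t <- res$time
  act <- activation(t, p[c("heart_rate", "t_sas", "t_svs", "t_pws")])
  P_ra <- chamber_pressure(st[, "V_ra"], act$A_a, chamber_par(p, "ra"))
  P_rv <- chamber_pressure(st[, "V_rv"], act$A_v, chamber_par(p, "rv"))
  P_la <- chamber_pressure(st[, "V_la"], act$A_a, chamber_par(p, "la"))
  P_lv <- chamber_pressure(st[, "V_lv"], act$A_v, chamber_par(p, "lv"))
  w <- list(
    time = t,
    P_ra = P_ra, P_rv = P_rv, P_la = P_la, P_lv = P_lv,
    P_ao = st[, "P_ao"], P_sys = st[, "P_sys"], P_pa = st[, "P_pa"],
    V_ra = st[, "V_ra"], V_rv = st[, "V_rv"],
    V_la = st[, "V_la"], V_lv = st[, "V_lv"],
    Q_ra_rv = st[, "Q_ra_rv"], Q_rv_pa = st[, "Q_rv_pa"],
    Q_la_lv = st[, "Q_la_lv"], Q_lv_ao = st[, "Q_lv_ao"],
    Q_sys_a = (st[, "P_ao"] - st[, "P_sys"]) / p[["R_sys_a"]],
    Q_sys_v = (st[, "P_sys"] - P_ra) / p[["R_sys_v"]],
    Q_pa = (st[, "P_pa"] - P_la) / p[["R_pa"]],
    phi_T = as.integer(P_ra > P_rv), phi_P = as.integer(P_rv > st[, "P_pa"]),
    phi_M = as.integer(P_la > P_lv), phi_A = as.integer(P_lv > st[, "P_ao"]),
    A_a = act$A_a, A_v = act$A_v,
    t_c = res$t_c, cycles = res$cycles, converged = res$converged,
    params = p)
  if (!res$converged)
    warning("periodic steady state not reached within ", config$max_cycles,
            " cycles", call. = FALSE)
  structure(w, class = "circ_waveforms")
}

#' @export
print.circ_waveforms <- function(x, ...) {
  cat("<circ_waveforms> one cardiac cycle, t_c =", format(x$t_c), "s,",
      length(x$time), "samples\n")
  cat("  cycles integrated:", x$cycles,
      if (isTRUE(x$converged)) "(converged)" else "(NOT converged)", "\n")
  cat(sprintf("  P_ao %.1f/%.1f mmHg, P_pa %.1f/%.1f mmHg, LV %.0f-%.0f mL\n",
              max(x$P_ao) / MMHG, min(x$P_ao) / MMHG,
              max(x$P_pa) / MMHG, min(x$P_pa) / MMHG,
              min(x$V_lv), max(x$V_lv)))
  invisible(x)
}

#' Export one cycle of waveforms as a data frame in clinical units
#'
#' Pressures are converted to mmHg; volumes and flows stay in mL and mL/s.
#'
#' @param w A \code{circ_waveforms} object.
#' @return A data frame with a \code{time} column, pressures, volumes, flows
#'   and valve indicators.
#' @export
waveforms_table <- function(w) {
  stopifnot(inherits(w, "circ_waveforms"))
  pr <- c("P_ra", "P_rv", "P_la", "P_lv", "P_ao", "P_sys", "P_pa")
  out <- data.frame(time = w$time)
  for (nm in pr) out[[nm]] <- w[[nm]] / MMHG
  for (nm in c("V_ra", "V_rv", "V_la", "V_lv", "Q_ra_rv", "Q_rv_pa",
               "Q_la_lv", "Q_lv_ao", "Q_sys_a", "Q_sys_v", "Q_pa",
               "phi_T", "phi_P", "phi_M", "phi_A"))
    out[[nm]] <- w[[nm]]
  out
}
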