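#' Clinical target dictionary
#'
#' The 26 EHR-style clinical targets the model can be trained on, with units
#' and the measurement standard deviation assumed for each (the
#' \code{lvot_max_flow} token has no assigned uncertainty and is excluded
#' from likelihoods by default).
#'
#' @return A data frame with columns \code{token}, \code{description},
#'   \code{units}, \code{sigma}.
#' @export
clinical_tokens <- function() {
  data.frame(
    token = c("heart_rate2", "systolic_bp_2", "diastolic_bp_2",
              "cardiac_output", "systemic_vascular_resistan",
              "pulmonary_vascular_resista", "cvp", "right_ventricle_diastole",
              "right_ventricle_systole", "rvedp", "aov_mean_pg",
              "aov_peak_pg", "mv_decel_time", "mv_e_a_ratio", "pv_at",
              "pv_max_pg", "ra_pressure", "ra_vol_a4c", "la_vol_a4c",
              "lv_esv", "lv_vol_a4c", "lvef", "lvot_max_flow",
              "pap_diastolic", "pap_systolic", "wedge_pressure"),
    description = c("Heart rate", "Systolic blood pressure",
                    "Diastolic blood pressure", "Cardiac output",
                    "Systemic vascular resistance",
                    "Pulmonary vascular resistance",
                    "Central venous pressure",
                    "Right ventricle diastolic pressure",
                    "Right ventricle systolic pressure",
                    "Right ventricle end-diastolic pressure",
                    "Mean PG across aortic valve",
                    "Peak PG across aortic valve",
                    "Mitral valve deceleration time", "Mitral valve E/A ratio",
                    "Pulmonary valve acceleration time",
                    "Peak PG across pulmonary valve",
                    "Mean right atrial pressure", "Right atrial volume",
                    "Left atrial volume", "LV end-systolic volume",
                    "Left ventricular volume", "LV ejection fraction",
                    "Peak LVOT flow", "Diastolic PAP", "Systolic PAP",
                    "Pulmonary wedge pressure"),
    units = c("bpm", "mmHg", "mmHg", "L/min", "dynes.s.cm-5", "dynes.s.cm-5",
              "mmHg", "mmHg", "mmHg", "mmHg", "mmHg", "mmHg", "ms", "-",
              "ms", "mmHg", "mmHg", "mL", "mL", "mL", "mL", "%", "mL/s",
              "mmHg", "mmHg", "mmHg"),
    sigma = c(3.0, 1.5, 1.5, 0.2, 50.0, 5.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.5,
              6.0, 0.2, 6.0, 0.5, 0.5, 3.0, 3.0, 10.0, 20.0, 2.0, NA,
              1.0, 1.0, 1.0),
    stringsAsFactors = FALSE)
}

#' Pulmonary target tokens
#'
#' Tokens withheld during pulmonary-blind training: systolic/diastolic PAP,
#' wedge pressure and pulmonary vascular resistance.
#' @return Character vector of four tokens.
#' @export
pulmonary_tokens <- function() {
  c("pap_systolic", "pap_diastolic", "wedge_pressure",
    "pulmonary_vascular_resista")
}

# circular index sequence from a to b (inclusive) over 1..n
circ_seq <- function(a, b, n) {
  if (a <= b) a:b else c(a:n, 1:b)
}

# cyclic 1 -> 0 transition indices of a 0/1 vector (first n samples)
falling_edges <- function(phi, n) {
  nxt <- c(2:n, 1)
  which(phi[1:n] == 1 & phi[nxt] == 0)
}
rising_edges <- function(phi, n) {
  nxt <- c(2:n, 1)
  which(phi[1:n] == 0 & phi[nxt] == 1)
}

#' Extract clinical targets from converged waveforms
#'
#' Maps one converged cardiac cycle to the 26 clinical tokens plus auxiliary
#' quantities used by the validation table (\code{lv_systole},
#' \code{lvedp}, \code{mpap}, \code{lvedv}). Pressures are reported in mmHg,
#' times in ms, volumes in mL, cardiac output in L/min and resistances in
#' dynes s cm-5. Landmark-based quantities (mitral E/A ratio, deceleration
#' time, pulmonary acceleration time) are set to \code{NA} when the landmark
#' cannot be found rather than raising an error.
#'
#' @param w A \code{circ_waveforms} object from \code{\link{simulate_model}}.
#' @param quantities Optional character vector restricting the computation
#'   (skips expensive landmark searches that are not requested).
#' @return Named numeric vector of extracted quantities.
#' @export
extract_targets <- function(w, quantities = NULL) {
  stopifnot(inherits(w, "circ_waveforms"))
  want <- function(q) is.null(quantities) || any(q %in% quantities)
  n <- length(w$time) - 1L          # periodic endpoint duplicated
  idx <- seq_len(n)
  p <- w$params
  m_pao <- mean(w$P_ao[idx]); m_pra <- mean(w$P_ra[idx])
  m_ppa <- mean(w$P_pa[idx]); m_pla <- mean(w$P_la[idx])
  lvedv <- max(w$V_lv); lvesv <- min(w$V_lv)
  hr <- p[["heart_rate"]]
  co <- hr * (lvedv - lvesv) / 1000            # L/min
  co_cgs <- co * 1000 / 60                     # mL/s

  out <- c(
    heart_rate2 = hr,
    systolic_bp_2 = max(w$P_ao) / MMHG,
    diastolic_bp_2 = min(w$P_ao) / MMHG,
    cardiac_output = co,
    systemic_vascular_resistan = (m_pao - m_pra) / co_cgs,
    pulmonary_vascular_resista = (m_ppa - m_pla) / co_cgs,
    cvp = m_pra / MMHG,
    right_ventricle_diastole = min(w$P_rv) / MMHG,
    right_ventricle_systole = max(w$P_rv) / MMHG,
    rvedp = NA_real_,
    aov_mean_pg = NA_real_, aov_peak_pg = NA_real_,
    mv_decel_time = NA_real_, mv_e_a_ratio = NA_real_,
    pv_at = NA_real_, pv_max_pg = NA_real_,
    ra_pressure = m_pra / MMHG,
    ra_vol_a4c = max(w$V_ra), la_vol_a4c = max(w$V_la),
    lv_esv = lvesv, lv_vol_a4c = lvedv,
    lvef = 100 * (lvedv - lvesv) / lvedv,
    lvot_max_flow = max(w$Q_lv_ao),
    pap_diastolic = min(w$P_pa) / MMHG,
    pap_systolic = max(w$P_pa) / MMHG,
    wedge_pressure = m_pla / MMHG,
    lv_systole = max(w$P_lv) / MMHG,
    lvedp = NA_real_,
    mpap = m_ppa / MMHG,
    lvedv = lvedv)

  # end-diastolic pressures: chamber pressure at inflow-valve closure (the
  # closure instant with the largest chamber volume if several exist); the
  # crossing of the transvalvular gradient is located by linear
  # interpolation between samples to avoid grid quantisation
  edp <- function(phi, P_up, P, V) {
    cl <- falling_edges(phi, n)
    if (!length(cl)) return(NA_real_)
    k <- cl[which.max(V[cl])]
    k2 <- if (k == n) 1L else k + 1L
    g1 <- P_up[k] - P[k]; g2 <- P_up[k2] - P[k2]
    a <- if (g1 > 0 && g2 < 0) g1 / (g1 - g2) else 0
    (P[k] + a * (P[k2] - P[k])) / MMHG
  }
  out[["rvedp"]] <- edp(w$phi_T, w$P_ra, w$P_rv, w$V_rv)
  out[["lvedp"]] <- edp(w$phi_M, w$P_la, w$P_lv, w$V_lv)

  # transvalvular gradients over ejection (instantaneous model pressures)
  ej_a <- which(w$phi_A[idx] == 1)
  if (length(ej_a)) {
    dg <- (w$P_lv[ej_a] - w$P_ao[ej_a]) / MMHG
    out[["aov_peak_pg"]] <- max(dg)
    out[["aov_mean_pg"]] <- mean(dg)
  }
  ej_p <- which(w$phi_P[idx] == 1)
  if (length(ej_p))
    out[["pv_max_pg"]] <- max((w$P_rv[ej_p] - w$P_pa[ej_p]) / MMHG)

  dt <- w$time[2] - w$time[1]

  # pulmonary acceleration time: valve opening to peak flow, ms
  op <- rising_edges(w$phi_P, n)
  clp <- falling_edges(w$phi_P, n)
  if (want("pv_at") && length(op) && length(clp)) {
    o <- op[1]
    cl <- clp[which(clp != o)]
    cl <- if (length(cl)) cl[which.min((cl - o) %% n)] else o
    seqp <- circ_seq((o %% n) + 1L, cl, n)
    if (length(seqp) > 1) {
      pk <- seqp[which.max(w$Q_rv_pa[seqp])]
      out[["pv_at"]] <- 1000 * dt * ((pk - o) %% n)
    }
  }

  # mitral inflow E/A and deceleration time
  om <- rising_edges(w$phi_M, n)
  cm <- falling_edges(w$phi_M, n)
  if (want(c("mv_e_a_ratio", "mv_decel_time")) &&
      length(om) && length(cm)) {
    # longest diastolic open interval
    best <- NULL; blen <- -1
    for (o in om) {
      cl <- cm[which.min((cm - o) %% n)]
      len <- (cl - o) %% n
      if (len > blen) { blen <- len; best <- c(o, cl) }
    }
    dia <- circ_seq((best[1] %% n) + 1L, best[2], n)
    if (length(dia) > 4) {
      aa <- w$A_a[dia] > 0
      # atrial activation onset inside diastole separates E and A waves
      a_on <- which(aa & !c(FALSE, aa[-length(aa)]))
      if (length(a_on) && a_on[1] > 2) {
        e_part <- dia[1:(a_on[1] - 1)]
        a_part <- dia[a_on[1]:length(dia)]
        qe <- w$Q_la_lv[e_part]; qa <- w$Q_la_lv[a_part]
        if (max(qa) > 0 && max(qe) > 0) {
          out[["mv_e_a_ratio"]] <- max(qe) / max(qa)
          # deceleration: line fit to the descending E limb (90%-30% of peak)
          ipk <- which.max(qe)
          post <- qe[ipk:length(qe)]
          sel <- which(post <= 0.9 * max(qe) & post >= 0.3 * max(qe))
          # stop at the first local re-acceleration
          if (length(sel) >= 2) {
            tt <- (ipk - 1 + sel - 1) * dt
            fit <- stats::lm.fit(cbind(1, tt), post[sel])
            sl <- fit$coefficients[2]
            if (is.finite(sl) && sl < 0) {
              t_zero <- -fit$coefficients[1] / sl
              out[["mv_decel_time"]] <- 1000 * (t_zero - (ipk - 1) * dt)
            }
          }
        }
      }
    }
  }
  out
}

#' Percent error between a clinical target and a model output
#'
#' \code{100 |target - output| / target}.
#'
#' @param target Non-zero reference value. @param output Model output.
#' @return Non-negative percent error.
#' @export
percent_error <- function(target, output) {
  if (any(target == 0)) stop("percent error undefined for zero target",
                             call. = FALSE)
  100 * abs(target - output) / abs(target)
}

#' Mean pulmonary pressure from systolic and diastolic values
#'
#' Standard clinical estimate \code{(sPAP + 2 dPAP) / 3}, used on the data
#' side when only systolic and diastolic pulmonary pressures are recorded.
#'
#' @param spap,dpap Systolic and diastolic pulmonary pressures, mmHg.
#' @return Estimated mean pulmonary pressure, mmHg.
#' @export
mpap_estimate <- function(spap, dpap) (spap + 2 * dpap) / 3
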