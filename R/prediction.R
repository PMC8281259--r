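#' Predict pulmonary quantities from pulmonary-blind training
#'
#' Removes the pulmonary tokens (systolic/diastolic PAP, wedge pressure,
#' pulmonary vascular resistance) from a patient's target set, samples the
#' posterior with DREAM on the remaining targets, propagates a posterior
#' subsample through the model, and summarises the predictive distribution
#' of the withheld pulmonary quantities.
#'
#' @param targets A \code{\link{target_set}} (may or may not contain
#'   pulmonary entries; any present are withheld and used only for error
#'   reporting).
#' @param prior,free,fixed,config As in \code{\link{dream_sample}}.
#' @param n_chains,n_iter,seed DREAM settings.
#' @param n_draws Number of posterior draws propagated.
#' @param ... Further arguments passed to \code{\link{dream_sample}}.
#' @return A list of class \code{"pulmonary_prediction"} with a
#'   \code{summary} data frame (quantity, mean, q05, q95, observed,
#'   abs_error), the predictive sample matrix, and \code{converged}.
#' @export
predict_pulmonary <- function(targets, prior = default_prior(),
                              free = default_free_mask(),
                              fixed = default_parameters("healthy"),
                              n_chains = 10, n_iter = 1000, seed = 1,
                              n_draws = 5000, config = sim_config(), ...) {
  stopifnot(inherits(targets, "target_set"))
  pulm <- pulmonary_tokens()
  train <- targets[!targets$name %in% pulm, , drop = FALSE]
  held <- targets[targets$name %in% pulm, , drop = FALSE]
  if (nrow(train) < 1)
    stop("no non-pulmonary targets available for training", call. = FALSE)
  class(train) <- class(targets)
  post <- dream_sample(train, prior = prior, free = free, fixed = fixed,
                       n_chains = n_chains, n_iter = n_iter, seed = seed,
                       n_subsample = n_draws, config = config, ...)
  qty <- c("pap_systolic", "pap_diastolic", "mpap", "wedge_pressure",
           "pulmonary_vascular_resista")
  pred <- propagate_outputs(post$subsample, qty, config)
  sm <- data.frame(
    quantity = qty,
    mean = colMeans(pred),
    q05 = apply(pred, 2, quantile, 0.05),
    q95 = apply(pred, 2, quantile, 0.95),
    observed = NA_real_, abs_error = NA_real_,
    row.names = NULL, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(held))) {
    k <- match(held$name[i], sm$quantity)
    sm$observed[k] <- held$value[i]
    sm$abs_error[k] <- abs(sm$mean[k] - held$value[i])
  }
  # mPAP observed via the clinical (s + 2d)/3 estimate when both recorded
  if (all(c("pap_systolic", "pap_diastolic") %in% held$name)) {
    k <- match("mpap", sm$quantity)
    sm$observed[k] <- mpap_estimate(
      held$value[held$name == "pap_systolic"],
      held$value[held$name == "pap_diastolic"])
    sm$abs_error[k] <- abs(sm$mean[k] - sm$observed[k])
  }
  structure(list(summary = sm, predictive = pred,
                 converged = post$converged, posterior = post),
            class = "pulmonary_prediction")
}

#' @export
print.pulmonary_prediction <- function(x, ...) {
  cat("<pulmonary_prediction>",
      if (x$converged) "(MCMC converged)" else "(MCMC not converged)", "\n")
  print(transform(x$summary, mean = round(mean, 2), q05 = round(q05, 2),
                  q95 = round(q95, 2), abs_error = round(abs_error, 2)))
  invisible(x)
}

#' Bland-Altman agreement statistics
#'
#' Mean difference (bias) and 95\% limits of agreement
#' \code{bias +/- 1.96 sd(pred - obs)}.
#'
#' @param pred,obs Equal-length numeric vectors (n >= 2).
#' @return Named vector \code{bias}, \code{loa_low}, \code{loa_high}.
#' @export
bland_altman <- function(pred, obs) {
  if (length(pred) != length(obs) || length(pred) < 2)
    stop("need equal-length vectors with at least 2 values", call. = FALSE)
  d <- pred - obs
  b <- mean(d); s <- sd(d)
  c(bias = b, loa_low = b - 1.96 * s, loa_high = b + 1.96 * s)
}

#' Average combined prediction error over available pulmonary targets
#'
#' Sum of the percent errors of the patient's available pulmonary targets
#' divided by their number \code{p}.
#'
#' @param outputs Named vector of model outputs.
#' @param pulmonary_observed Named vector of observed pulmonary values
#'   (subset of \code{\link{pulmonary_tokens}}).
#' @return Scalar percent error.
#' @export
combined_error <- function(outputs, pulmonary_observed) {
  po <- pulmonary_observed[!is.na(pulmonary_observed)]
  po <- po[names(po) %in% pulmonary_tokens()]
  p <- length(po)
  if (p < 1) stop("no pulmonary observations available", call. = FALSE)
  sum(percent_error(po, outputs[names(po)])) / p
}

#' Greedy forward ranking of non-pulmonary targets
#'
#' Ranks a patient's available non-pulmonary targets by their value for
#' predicting the pulmonary quantities: at each step, every unranked
#' candidate is temporarily added to the selected training set, a fast
#' Nelder-Mead fit is run, and the candidate minimising the average
#' combined prediction error on the patient's pulmonary observations is
#' ranked next (ties broken by dictionary order of the tokens).
#'
#' @param targets The patient's full \code{\link{target_set}} (must include
#'   at least one pulmonary observation and one non-pulmonary target).
#' @param prior,free,fixed,config As in \code{\link{map_estimate}}.
#' @param n_restarts,maxit Nelder-Mead budget per candidate fit.
#' @param seed Integer seed.
#' @return A list of class \code{"ranking_result"}: \code{ranking}
#'   (data frame with \code{rank}, \code{token}, \code{error}).
#' @export
rank_targets <- function(targets, prior = default_prior(),
                         free = default_free_mask(),
                         fixed = default_parameters("healthy"),
                         n_restarts = 5, maxit = 500, seed = 1,
                         config = sim_config()) {
  stopifnot(inherits(targets, "target_set"))
  pulm <- pulmonary_tokens()
  held <- targets[targets$name %in% pulm, , drop = FALSE]
  cand <- targets$name[!targets$name %in% pulm]
  if (nrow(held) < 1) stop("patient has no pulmonary observation",
                           call. = FALSE)
  if (length(cand) < 1) stop("patient has no non-pulmonary targets",
                             call. = FALSE)
  pulm_obs <- stats::setNames(held$value, held$name)
  token_order <- c(clinical_tokens()$token, "lv_systole", "lvedp")
  selected <- character(0)
  ranking <- data.frame(rank = integer(0), token = character(0),
                        error = numeric(0), stringsAsFactors = FALSE)
  step_seed <- seed
  while (length(cand)) {
    errs <- rep(NA_real_, length(cand))
    for (k in seq_along(cand)) {
      trial <- targets[targets$name %in% c(selected, cand[k]), ,
                       drop = FALSE]
      class(trial) <- class(targets)
      fit <- try(map_estimate(trial, prior = prior, free = free,
                              fixed = fixed, n_restarts = n_restarts,
                              seed = step_seed + k, init = fixed,
                              maxit = maxit, config = config),
                 silent = TRUE)
      if (inherits(fit, "try-error")) next
      errs[k] <- combined_error(fit$outputs, pulm_obs)
    }
    if (all(is.na(errs))) break
    # argmin with dictionary-order tie-break
    best <- which(errs == min(errs, na.rm = TRUE))
    if (length(best) > 1)
      best <- best[order(match(cand[best], token_order))][1]
    ranking <- rbind(ranking,
                     data.frame(rank = nrow(ranking) + 1L,
                                token = cand[best], error = errs[best],
                                stringsAsFactors = FALSE))
    selected <- c(selected, cand[best])
    cand <- cand[-best]
    step_seed <- step_seed + 100
  }
  structure(list(ranking = ranking, selected = selected),
            class = "ranking_result")
}

#' Aggregate per-patient rankings over a cohort
#'
#' @param rankings List of \code{"ranking_result"} objects.
#' @return Data frame with per-token mean rank and occurrence count,
#'   ordered by mean rank.
#' @export
aggregate_rankings <- function(rankings) {
  rows <- do.call(rbind, lapply(rankings, `[[`, "ranking"))
  agg <- stats::aggregate(rank ~ token, rows, mean)
  occ <- stats::aggregate(rank ~ token, rows, length)
  out <- data.frame(token = agg$token, mean_rank = agg$rank,
                    occurrences = occ$rank, stringsAsFactors = FALSE)
  out[order(out$mean_rank), ]
}
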