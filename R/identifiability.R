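#' Forward-difference relative sensitivity of a scalar map
#'
#' \code{(f(y(1 + h)) - f(y)) / (h f(y))}: the relative output change per
#' unit relative parameter change at relative step \code{h}.
#'
#' @param f Scalar function of a scalar.
#' @param y Evaluation point (nonzero, with \code{f(y)} nonzero).
#' @param rel_step Relative step (default 0.01).
#' @return Scalar sensitivity.
#' @export
relative_sensitivity <- function(f, y, rel_step = 0.01) {
  o0 <- f(y)
  if (o0 == 0 || y == 0) stop("zero output or parameter", call. = FALSE)
  dy <- rel_step * y
  ((f(y + dy) - o0) / dy) * (y / o0)
}

#' Central-difference Jacobian of a vector map
#'
#' @param f Function mapping a numeric vector to a numeric vector.
#' @param y Evaluation point.
#' @param rel_step Relative step (absolute for zero entries).
#' @return Matrix \code{length(y)} x \code{length(f(y))} (rows =
#'   parameters), i.e. \code{dG/dy} in the orientation used by
#'   \code{\link{fim_from_jacobian}}.
#' @export
num_jacobian <- function(f, y, rel_step = 0.01) {
  g0 <- f(y)
  J <- matrix(NA_real_, length(y), length(g0))
  for (j in seq_along(y)) {
    step <- if (y[j] != 0) rel_step * abs(y[j]) else rel_step
    up <- y; up[j] <- y[j] + step
    dn <- y; dn[j] <- y[j] - step
    J[j, ] <- (f(up) - f(dn)) / (2 * step)
  }
  J
}

#' Fisher information matrix from a Jacobian and target uncertainties
#'
#' \code{I = J B J^T} with \code{B = diag(1/sigma^2)}.
#'
#' @param J Jacobian, parameters x outputs.
#' @param sigmas Per-output standard deviations.
#' @return Symmetric positive semi-definite matrix.
#' @export
fim_from_jacobian <- function(J, sigmas) {
  B <- diag(1 / sigmas^2, nrow = length(sigmas))
  FIM <- J %*% B %*% t(J)
  (FIM + t(FIM)) / 2
}

#' Local relative sensitivities at a MAP point
#'
#' Forward-difference non-dimensional sensitivities
#' \code{(delta o_i / delta y_j) (y_j / o_i)} at a 1\% relative parameter
#' step: the relative change in each model output per 1\% change in each
#' free parameter. The report view rescales the absolute values of each row
#' (output) so it sums to 100.
#'
#' @param params MAP parameter vector (full 45-vector).
#' @param targets A \code{\link{target_set}} naming the outputs of interest.
#' @param free Logical mask of parameters to perturb.
#' @param rel_step Relative step (default 0.01).
#' @param config Simulation configuration.
#' @return A list of class \code{"sensitivity_table"} with matrices
#'   \code{raw} and \code{scaled} (outputs x parameters).
#' @export
local_sensitivity <- function(params, targets, free = default_free_mask(),
                              rel_step = 0.01, config = sim_config()) {
  p <- validate_parameters(params)
  o0 <- extract_targets(suppressWarnings(simulate_model(p, config)))
  out_names <- targets$name
  o0 <- o0[out_names]
  if (any(is.na(o0) | o0 == 0))
    stop("MAP outputs unavailable or zero for: ",
         paste(out_names[is.na(o0) | o0 == 0], collapse = ", "),
         call. = FALSE)
  fr <- which(free[parameter_names()])
  S <- matrix(NA_real_, length(out_names), length(fr),
              dimnames = list(out_names, parameter_names()[fr]))
  for (j in seq_along(fr)) {
    dp <- p
    step <- rel_step * p[fr[j]]
    if (step == 0) { S[, j] <- 0; next }
    dp[fr[j]] <- p[fr[j]] + step
    oj <- tryCatch(
      extract_targets(suppressWarnings(simulate_model(dp, config))),
      error = function(e) NULL)
    if (is.null(oj)) { S[, j] <- NA; next }
    S[, j] <- ((oj[out_names] - o0) / step) * (p[fr[j]] / o0)
  }
  A <- abs(S)
  rs <- rowSums(A, na.rm = TRUE)
  scaled <- 100 * A / ifelse(rs > 0, rs, NA)
  structure(list(raw = S, scaled = scaled), class = "sensitivity_table")
}

#' Average sensitivity tables over a cohort of MAP points
#'
#' @param tables List of \code{"sensitivity_table"} objects on identical
#'   output/parameter grids.
#' @return A \code{"sensitivity_table"} whose raw matrix is the elementwise
#'   mean and whose scaled view is recomputed from it.
#' @export
average_sensitivities <- function(tables) {
  stopifnot(length(tables) >= 1)
  raws <- lapply(tables, `[[`, "raw")
  R <- Reduce(`+`, raws) / length(raws)
  A <- abs(R)
  rs <- rowSums(A, na.rm = TRUE)
  structure(list(raw = R, scaled = 100 * A / ifelse(rs > 0, rs, NA)),
            class = "sensitivity_table")
}

#' Fisher information matrix at a MAP point
#'
#' \code{I = J B J^T} with \code{J = dG/dy} (free parameters x outputs, by
#' central differences at a relative step) and \code{B} the diagonal
#' precision matrix \code{1/sigma_i^2} of the available targets. Rank
#' deficiency (near-zero eigenvalues) flags non-identifiable parameter
#' combinations.
#'
#' @inheritParams local_sensitivity
#' @param cutoff Eigenvalue threshold below which eigenvectors are flagged.
#' @return A list of class \code{"fim_report"}: \code{fim},
#'   \code{eigenvalues} (ascending), \code{eigenvectors} (columns matching),
#'   \code{flagged} (indices with eigenvalue < cutoff), \code{cutoff}.
#' @export
fisher_information <- function(params, targets, free = default_free_mask(),
                               rel_step = 0.01, cutoff = 1e-13,
                               config = sim_config()) {
  p <- validate_parameters(params)
  fr <- which(free[parameter_names()])
  out_names <- targets$name
  J <- matrix(NA_real_, length(fr), length(out_names),
              dimnames = list(parameter_names()[fr], out_names))
  for (j in seq_along(fr)) {
    step <- rel_step * p[fr[j]]
    if (step == 0) step <- rel_step  # absolute fallback for zero entries
    up <- p; up[fr[j]] <- p[fr[j]] + step
    dn <- p; dn[fr[j]] <- p[fr[j]] - step
    gu <- tryCatch(
      extract_targets(suppressWarnings(simulate_model(up, config))),
      error = function(e) NULL)
    gd <- tryCatch(
      extract_targets(suppressWarnings(simulate_model(dn, config))),
      error = function(e) NULL)
    if (is.null(gu) || is.null(gd))
      stop("estimation failed: simulation error while differencing ",
           parameter_names()[fr[j]], call. = FALSE)
    J[j, ] <- (gu[out_names] - gd[out_names]) / (2 * step)
  }
  FIM <- fim_from_jacobian(J, targets$sigma)
  ed <- eigen(FIM, symmetric = TRUE)
  ord <- order(ed$values)
  ev <- ed$values[ord]; V <- ed$vectors[, ord, drop = FALSE]
  rownames(V) <- rownames(J)
  structure(list(fim = FIM, eigenvalues = ev, eigenvectors = V,
                 flagged = which(ev < cutoff), cutoff = cutoff),
            class = "fim_report")
}

#' Learning factor and coefficient of variation per parameter
#'
#' The learning factor \code{theta_j = 1 - Var_post(y_j) / Var_prior(y_j)}
#' quantifies how much conditioning on the data shrinks each marginal
#' (prior variance of a uniform box entry is \code{(b-a)^2/12});
#' \code{CV_j = sd_post / |mean_post|}.
#'
#' @param posterior_samples Matrix of posterior draws (rows) by parameter
#'   columns (named).
#' @param prior Prior box list (\code{lo}, \code{hi}).
#' @return Data frame with columns \code{parameter}, \code{theta},
#'   \code{cv}.
#' @export
learning_factor <- function(posterior_samples, prior = default_prior()) {
  stopifnot(nrow(posterior_samples) >= 100)
  nm <- colnames(posterior_samples)
  lo <- prior$lo[nm]; hi <- prior$hi[nm]
  if (any(hi - lo <= 0)) stop("zero prior width", call. = FALSE)
  vprior <- (hi - lo)^2 / 12
  vpost <- apply(posterior_samples, 2, var)
  mpost <- colMeans(posterior_samples)
  data.frame(parameter = nm,
             theta = 1 - vpost / vprior,
             cv = sqrt(vpost) / abs(mpost),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Kullback-Leibler divergence of an assumed Gaussian from a predicted
#' density
#'
#' Computes \code{KL(N(mu, sigma) || q)} by trapezoidal integration on a
#' grid spanning \code{mu +/- 6 sigma}, with the predicted density \code{q}
#' clipped at 1e-12 before the logarithm.
#'
#' @param mu,sigma Mean and standard deviation of the assumed target
#'   distribution.
#' @param density_fun Function returning the predicted density at a vector
#'   of points.
#' @param n_grid Number of integration nodes.
#' @return Non-negative KL divergence (nats).
#' @export
kl_gaussian_vs_density <- function(mu, sigma, density_fun, n_grid = 2001) {
  x <- seq(mu - 6 * sigma, mu + 6 * sigma, length.out = n_grid)
  p <- dnorm(x, mu, sigma)
  q <- pmax(density_fun(x), 1e-12)
  f <- ifelse(p > 0, p * log(p / q), 0)
  h <- x[2] - x[1]
  max(0, sum((f[-1] + f[-n_grid]) / 2) * h)
}

#' KL admissibility of posterior-predictive samples
#'
#' For each target, compares the assumed Gaussian \code{N(mu, sigma)} with a
#' Gaussian kernel density estimate (Scott's bandwidth) of the
#' posterior-predictive samples; small divergences indicate that the
#' trained model reproduces the assumed target distribution.
#'
#' @param predictive Matrix of posterior-predictive samples (draws x
#'   targets, columns named).
#' @param targets A \code{\link{target_set}} with the assumed means and
#'   standard deviations.
#' @return Named numeric vector of KL divergences (nats), one per target.
#' @export
kl_admissibility <- function(predictive, targets) {
  stopifnot(nrow(predictive) >= 100)
  vapply(seq_len(nrow(targets)), function(i) {
    s <- predictive[, targets$name[i]]
    s <- s[is.finite(s)]
    if (length(unique(s)) < 2)
      stop("degenerate predictive sample for ", targets$name[i],
           call. = FALSE)
    mu <- targets$value[i]; sg <- targets$sigma[i]
    kde <- stats::density(s, bw = stats::bw.nrd(s),
                          from = mu - 6 * sg, to = mu + 6 * sg, n = 2001)
    qf <- function(x) stats::approx(kde$x, kde$y, xout = x,
                                    yleft = 0, yright = 0)$y
    kl_gaussian_vs_density(mu, sg, qf)
  }, numeric(1), USE.NAMES = FALSE) -> kl
  stats::setNames(kl, targets$name)
}

#' Propagate posterior draws to model outputs
#'
#' Simulates each draw and extracts clinical quantities, yielding the
#' posterior-predictive sample matrix used by admissibility and
#' pulmonary-prediction analyses.
#'
#' @param draws Matrix of full 45-parameter rows (e.g.
#'   \code{posterior$subsample}).
#' @param quantities Character vector of extraction names to keep.
#' @param config Simulation configuration.
#' @return Matrix (successful draws x quantities).
#' @export
propagate_outputs <- function(draws, quantities, config = sim_config()) {
  res <- matrix(NA_real_, nrow(draws), length(quantities),
                dimnames = list(NULL, quantities))
  for (i in seq_len(nrow(draws))) {
    g <- tryCatch(
      extract_targets(suppressWarnings(simulate_model(draws[i, ], config))),
      error = function(e) NULL)
    if (!is.null(g)) res[i, ] <- g[quantities]
  }
  res[stats::complete.cases(res), , drop = FALSE]
}
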