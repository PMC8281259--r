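#' Build a clinical target set
#'
#' A target set pairs measured clinical values with their assumed Gaussian
#' measurement standard deviations. Names must be extractable quantities
#' (clinical tokens or validation quantities such as \code{lv_systole},
#' \code{lvedp}).
#'
#' @param values Named numeric vector of measured targets.
#' @param sigmas Named numeric vector of standard deviations; defaults to the
#'   dictionary values from \code{\link{clinical_tokens}} where available.
#' @return A data frame of class \code{"target_set"} with columns
#'   \code{name}, \code{value}, \code{sigma}.
#' @export
target_set <- function(values, sigmas = NULL) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  values <- values[!is.na(values)]
  if (length(values) < 1) stop("empty target set", call. = FALSE)
  if (is.null(sigmas)) {
    tok <- clinical_tokens()
    sigmas <- stats::setNames(tok$sigma, tok$token)[names(values)]
  } else sigmas <- unlist(sigmas)[names(values)]
  if (any(is.na(sigmas) | sigmas <= 0))
    stop("every target needs a positive sigma; missing for: ",
         paste(names(values)[is.na(sigmas) | sigmas <= 0], collapse = ", "),
         call. = FALSE)
  structure(data.frame(name = names(values), value = unname(values),
                       sigma = unname(sigmas), stringsAsFactors = FALSE),
            class = c("target_set", "data.frame"))
}

#' Gaussian log-likelihood of a parameter vector
#'
#' Independent-Gaussian measurement model: for the \code{m} available
#' targets, \code{log L = -(m/2) log 2 pi - sum(log sigma_i)
#' - 1/2 sum((d_i - G_i(y))^2 / sigma_i^2)}. Simulations that diverge or do
#' not reach a periodic steady state score \code{-Inf}, as do parameter
#' vectors whose model outputs lack a requested landmark.
#'
#' @param params Named 45-parameter vector.
#' @param targets A \code{\link{target_set}}.
#' @param config A \code{\link{sim_config}}.
#' @param outputs Optional precomputed output vector (skips simulation).
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(params, targets, config = sim_config(),
                           outputs = NULL) {
  stopifnot(inherits(targets, "target_set"))
  if (nrow(targets) < 1) stop("empty target set", call. = FALSE)
  if (is.null(outputs)) {
    w <- tryCatch(suppressWarnings(simulate_model(params, config)),
                  cardiolpn_diverged = function(e) NULL)
    if (is.null(w) || !isTRUE(w$converged)) return(-Inf)
    outputs <- extract_targets(w, targets$name)
  }
  g <- outputs[targets$name]
  if (any(is.na(g))) return(-Inf)
  m <- nrow(targets)
  -(m / 2) * log(2 * pi) - sum(log(targets$sigma)) -
    0.5 * sum(((targets$value - g) / targets$sigma)^2)
}

# normalized coordinates: u in [0,1]^d over the free parameters
make_log_posterior <- function(targets, prior = default_prior(),
                               free = default_free_mask(),
                               fixed = default_parameters("healthy"),
                               config = sim_config()) {
  nm <- parameter_names()
  free <- free[nm]; lo <- prior$lo[nm]; hi <- prior$hi[nm]
  base <- validate_parameters(fixed)
  fr <- which(free)
  to_params <- function(u) {
    y <- base
    y[fr] <- lo[fr] + u * (hi[fr] - lo[fr])
    y
  }
  lp <- function(u) {
    if (any(u < 0 | u > 1)) return(-Inf)
    y <- to_params(u)
    tryCatch(log_likelihood(y, targets, config), error = function(e) -Inf)
  }
  list(lp = lp, to_params = to_params, d = length(fr), free_idx = fr,
       lo = lo, hi = hi)
}

# generic best-of-restarts Nelder-Mead minimizer; starts = matrix of rows
nm_multistart <- function(neg, starts, maxit = 2000, reltol = 1e-6) {
  best <- NULL; best_val <- Inf; trace <- numeric(0); n_eval <- 0L
  for (r in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[r, ], neg, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = reltol))
    n_eval <- n_eval + fit$counts[["function"]]
    if (fit$value < best_val) { best_val <- fit$value; best <- fit$par }
    trace <- c(trace, best_val)
  }
  list(best = best, value = best_val, trace = trace, n_eval = n_eval)
}

#' Maximum a posteriori estimation by repeated Nelder-Mead
#'
#' Maximizes the Gaussian log-posterior (uniform box prior) over the free
#' parameters with multiple Nelder-Mead restarts. Restart starting points
#' are drawn uniformly from the prior box with the given seed; additional
#' warm-start points (e.g. the best MCMC sample or a physiological anchor)
#' can be supplied via \code{init}.
#'
#' @param targets A \code{\link{target_set}}.
#' @param prior Prior box (list with \code{lo}, \code{hi}).
#' @param free Logical free/frozen mask over the 45 parameters.
#' @param fixed Parameter vector supplying frozen values.
#' @param n_restarts Number of uniform restarts (>= 1).
#' @param seed Integer seed controlling the restart draws.
#' @param init Optional matrix (rows = extra starting points, full
#'   45-parameter scale) or a single named vector.
#' @param maxit Nelder-Mead evaluation cap per restart.
#' @param config Simulation configuration.
#' @return A list of class \code{"map_result"}: \code{params} (full
#'   45-vector), \code{outputs}, \code{log_posterior}, \code{trace}
#'   (best-so-far value after each restart), \code{n_eval}.
#' @export
map_estimate <- function(targets, prior = default_prior(),
                         free = default_free_mask(),
                         fixed = default_parameters("healthy"),
                         n_restarts = 20, seed = 1, init = NULL,
                         maxit = 2000, config = sim_config()) {
  stopifnot(n_restarts >= 1)
  ctx <- make_log_posterior(targets, prior, free, fixed, config)
  d <- ctx$d
  neg <- function(u) {
    if (any(u < 0 | u > 1))
      return(1e8 * (1 + sum(pmax(0, u - 1) + pmax(0, -u))))
    v <- ctx$lp(u)
    if (!is.finite(v)) 1e7 else -v
  }
  set.seed(seed)
  starts <- matrix(runif(n_restarts * d), n_restarts, d)
  if (!is.null(init)) {
    if (is.null(dim(init))) init <- matrix(init, 1,
                                           dimnames = list(NULL, names(init)))
    ui <- t(apply(init, 1, function(y) {
      y <- y[parameter_names()]
      (y[ctx$free_idx] - ctx$lo[ctx$free_idx]) /
        (ctx$hi[ctx$free_idx] - ctx$lo[ctx$free_idx])
    }))
    ui <- pmin(pmax(ui, 0), 1)
    starts <- rbind(ui, starts)
  }
  nm <- nm_multistart(neg, starts, maxit)
  best <- nm$best; best_val <- nm$value; trace <- nm$trace
  n_eval <- nm$n_eval
  if (!is.finite(best_val) || best_val >= 1e7)
    stop("estimation failed: no restart produced a converged simulation",
         call. = FALSE)
  y <- ctx$to_params(best)
  w <- suppressWarnings(simulate_model(y, config))
  structure(list(params = y, outputs = extract_targets(w),
                 log_posterior = -best_val, trace = -trace,
                 n_eval = n_eval, targets = targets),
            class = "map_result")
}

#' @export
print.map_result <- function(x, ...) {
  cat("<map_result> log-posterior", format(x$log_posterior),
      "after", x$n_eval, "evaluations\n")
  g <- x$outputs[x$targets$name]
  err <- percent_error(x$targets$value, g)
  cat("  max percent error over", nrow(x$targets), "targets:",
      sprintf("%.2f%%", max(err)), "\n")
  invisible(x)
}

#' Gelman-Rubin convergence diagnostic
#'
#' Potential scale reduction factor
#' \code{R_hat = sqrt((((n-1)/n) W + B/n) / W)} with \code{W} the mean
#' within-chain variance and \code{B} the between-chain variance.
#'
#' @param chains Either a numeric matrix (iterations x chains) for one
#'   parameter, or a 3-d array (iterations x chains x parameters).
#' @return Numeric vector of R-hat values (one per parameter).
#' @export
gelman_rubin <- function(chains) {
  if (length(dim(chains)) == 2) chains <- array(chains, c(dim(chains), 1))
  n <- dim(chains)[1]; m <- dim(chains)[2]
  if (m < 2 || n < 2) stop("need >= 2 chains with >= 2 samples",
                           call. = FALSE)
  apply(chains, 3, function(x) {
    W <- mean(apply(x, 2, var))
    if (W == 0) stop("zero within-chain variance: R-hat undefined",
                     call. = FALSE)
    B <- n * var(colMeans(x))
    sqrt((((n - 1) / n) * W + B / n) / W)
  })
}

#' Differential-evolution adaptive Metropolis (DREAM) sampling
#'
#' Samples the Gaussian-likelihood, uniform-box-prior posterior with the
#' DREAM algorithm: multi-chain differential-evolution proposals
#' \code{z = x + (1 + e) gamma(delta, d') (sum x_a - sum x_b) + eps} on a
#' crossover-selected parameter subspace, with \code{gamma = 2.38 /
#' sqrt(2 delta d')} (unit jumps with probability \code{p_g} for mode
#' hopping), adaptive crossover probabilities during burn-in, outlier-chain
#' replacement by an IQR rule on second-half mean log-posterior, and
#' Gelman-Rubin monitoring on the post-burn-in half.
#'
#' @inheritParams map_estimate
#' @param n_chains Number of parallel chains (>= 3).
#' @param n_iter Generations per chain.
#' @param seed Integer seed.
#' @param init Chain initialisation: \code{"prior"} (uniform draws from the
#'   prior box) or a matrix of full 45-parameter rows (recycled, jittered).
#' @param delta_max Maximum number of chain pairs per proposal.
#' @param n_cr Number of crossover values.
#' @param p_g Probability of a unit-gamma (mode-hopping) jump.
#' @param b_lambda Half-width of the multiplicative jitter \code{e}.
#' @param b_star Standard deviation of the additive proposal noise
#'   (normalized units).
#' @param rhat_threshold Convergence threshold on R-hat.
#' @param n_subsample Size of the posterior subsample returned.
#' @param reflect Reflect out-of-box proposals back into the box instead of
#'   rejecting them through the prior.
#' @return A list of class \code{"posterior"}: \code{chains} (kept
#'   iterations x chains x free parameters, original scale),
#'   \code{log_posterior}, \code{rhat}, \code{converged},
#'   \code{subsample} (draws x 45 full parameter vectors; outlier chains
#'   failing the IQR rule on kept-half mean log-posterior are excluded
#'   from the subsample, though retained in \code{chains}),
#'   \code{acceptance}, \code{free_names}.
#' @export
dream_sample <- function(targets, prior = default_prior(),
                         free = default_free_mask(),
                         fixed = default_parameters("healthy"),
                         n_chains = 10, n_iter = 1000, seed = 1,
                         init = "prior", delta_max = 3, n_cr = 3,
                         p_g = 0.1, b_lambda = 0.1, b_star = 1e-6,
                         rhat_threshold = 1.1, n_subsample = 5000,
                         reflect = FALSE, config = sim_config()) {
  stopifnot(n_chains >= 3, n_iter >= 10)
  ctx <- make_log_posterior(targets, prior, free, fixed, config)
  d <- ctx$d
  set.seed(seed)
  if (is.character(init)) {
    X <- matrix(runif(n_chains * d), n_chains, d)
  } else {
    if (is.null(dim(init))) init <- matrix(init, 1,
                                           dimnames = list(NULL, names(init)))
    U <- t(apply(init, 1, function(y) {
      y <- y[parameter_names()]
      (y[ctx$free_idx] - ctx$lo[ctx$free_idx]) /
        (ctx$hi[ctx$free_idx] - ctx$lo[ctx$free_idx])
    }))
    X <- U[rep_len(seq_len(nrow(U)), n_chains), , drop = FALSE]
    X <- X + matrix(rnorm(n_chains * d, 0, 0.01), n_chains, d)
    X <- pmin(pmax(X, 0), 1)
  }
  core <- dream_core(ctx$lp, X, n_iter, delta_max = delta_max,
                     n_cr = n_cr, p_g = p_g, b_lambda = b_lambda,
                     b_star = b_star, reflect = reflect)
  chains <- core$chains; lps <- core$lps
  acc <- core$acc; tot <- core$tot
  rhat <- tryCatch(gelman_rubin(chains), error = function(e)
    rep(NA_real_, dim(core$chains)[3]))
  converged <- all(is.finite(rhat)) && all(rhat < rhat_threshold)
  # map back to original scale
  fr <- ctx$free_idx
  scale <- ctx$hi[fr] - ctx$lo[fr]
  chains_orig <- chains
  for (j in seq_len(d))
    chains_orig[, , j] <- ctx$lo[fr][j] + chains[, , j] * scale[j]
  keep <- dim(chains)[1]
  # outlier chains (IQR rule on kept-half mean log-posterior) stay in the
  # chains array for diagnostics but are excluded from the subsample
  mlp <- colMeans(lps)
  fin <- mlp[is.finite(mlp)]
  good <- seq_len(n_chains)
  if (length(fin) >= 3) {
    qq <- quantile(fin, c(0.25, 0.75))
    thr <- qq[1] - 2 * (qq[2] - qq[1])
    good2 <- which(is.finite(mlp) & mlp >= thr)
    if (length(good2) >= 3) good <- good2
  }
  flat <- matrix(aperm(chains[, good, , drop = FALSE], c(1, 2, 3)),
                 keep * length(good), d)
  flat_lp <- as.vector(lps[, good, drop = FALSE])
  ok <- is.finite(flat_lp)
  ns <- min(n_subsample, sum(ok))
  pick <- sample(which(ok), ns, replace = sum(ok) < n_subsample)
  sub <- t(apply(flat[pick, , drop = FALSE], 1, ctx$to_params))
  colnames(sub) <- parameter_names()
  structure(list(chains = chains_orig, log_posterior = lps, rhat = rhat,
                 converged = converged, subsample = sub,
                 subsample_log_posterior = flat_lp[pick],
                 acceptance = acc / tot,
                 free_names = parameter_names()[fr],
                 prior = prior, fixed = validate_parameters(fixed),
                 free = free, targets = targets),
            class = "posterior")
}

# Generic DREAM sampling core on [0,1]^d (or unconstrained when
# reflect = FALSE and lp handles bounds itself). X0: chains x d start
# matrix; lp: log-density function of one row.
dream_core <- function(lp_fun, X0, n_iter, delta_max = 3, n_cr = 3,
                       p_g = 0.1, b_lambda = 0.1, b_star = 1e-6,
                       reflect = FALSE) {
  X <- as.matrix(X0)
  n_chains <- nrow(X); d <- ncol(X)
  lp <- apply(X, 1, lp_fun)
  # chains stuck at -Inf never move through DE jumps alone; nudge by redraw
  for (i in which(!is.finite(lp))) {
    for (k in seq_len(20)) {
      X[i, ] <- runif(d); lp[i] <- lp_fun(X[i, ])
      if (is.finite(lp[i])) break
    }
  }
  delta_max <- max(1L, min(delta_max, (n_chains - 1L) %/% 2L))
  crs <- seq_len(n_cr) / n_cr
  p_cr <- rep(1 / n_cr, n_cr)
  delta_acc <- rep(0, n_cr); cnt_cr <- rep(0, n_cr)
  burn <- floor(n_iter / 2)
  keep <- n_iter - burn
  chains <- array(NA_real_, c(keep, n_chains, d))
  lps <- matrix(NA_real_, keep, n_chains)
  acc <- 0L; tot <- 0L
  hist_lp <- matrix(NA_real_, n_iter, n_chains)

  for (it in seq_len(n_iter)) {
    for (i in seq_len(n_chains)) {
      delta <- sample.int(delta_max, 1)
      others <- setdiff(seq_len(n_chains), i)
      r <- sample(others, 2 * delta)
      a <- r[seq_len(delta)]; b <- r[delta + seq_len(delta)]
      mcr <- sample.int(n_cr, 1, prob = p_cr)
      sel <- runif(d) < crs[mcr]
      if (!any(sel)) sel[sample.int(d, 1)] <- TRUE
      dp <- sum(sel)
      gamma <- if (runif(1) < p_g) 1 else 2.38 / sqrt(2 * delta * dp)
      e <- runif(dp, -b_lambda, b_lambda)
      jump <- (1 + e) * gamma *
        (colSums(X[a, , drop = FALSE])[sel] -
           colSums(X[b, , drop = FALSE])[sel]) + rnorm(dp, 0, b_star)
      z <- X[i, ]
      z[sel] <- z[sel] + jump
      if (reflect) {
        z <- abs(z); z <- ifelse(z > 1, 2 - z, z)
        z <- pmin(pmax(z, 0), 1)
      }
      lpz <- lp_fun(z)
      tot <- tot + 1L
      if (is.finite(lpz) && log(runif(1)) < lpz - lp[i]) {
        if (it <= burn) {
          sdx <- pmax(apply(X, 2, sd), 1e-12)
          delta_acc[mcr] <- delta_acc[mcr] +
            sum(((z - X[i, ]) / sdx)^2)
        }
        X[i, ] <- z; lp[i] <- lpz
        acc <- acc + 1L
      }
      if (it <= burn) cnt_cr[mcr] <- cnt_cr[mcr] + 1
    }
    hist_lp[it, ] <- lp
    # adaptive crossover probabilities and outlier handling during burn-in
    if (it <= burn && it %% 25 == 0) {
      if (sum(delta_acc) > 0) {
        p_cr <- (delta_acc / pmax(cnt_cr, 1))
        p_cr <- p_cr / sum(p_cr)
        p_cr <- pmax(p_cr, 0.05); p_cr <- p_cr / sum(p_cr)
      }
      half <- hist_lp[max(1, floor(it / 2)):it, , drop = FALSE]
      mlp <- colMeans(half)
      fin <- mlp[is.finite(mlp)]
      if (length(fin) >= 3) {
        q <- quantile(fin, c(0.25, 0.75))
        thr <- q[1] - 2 * (q[2] - q[1])
        out <- which(!is.finite(mlp) | mlp < thr)
      } else out <- integer(0)
      if (length(out) && length(out) < n_chains) {
        bi <- which.max(lp)
        for (o in out) { X[o, ] <- X[bi, ]; lp[o] <- lp[bi] }
      }
    }
    if (it > burn) {
      chains[it - burn, , ] <- X
      lps[it - burn, ] <- lp
    }
  }
  list(chains = chains, lps = lps, acc = acc, tot = tot)
}

#' @export
print.posterior <- function(x, ...) {
  d <- dim(x$chains)
  cat("<posterior>", d[2], "chains x", d[1], "kept iterations,",
      d[3], "free parameters\n")
  cat("  acceptance:", sprintf("%.1f%%", 100 * x$acceptance),
      " max R-hat:", sprintf("%.3f", max(x$rhat)),
      if (x$converged) "(converged)" else "(not converged)", "\n")
  invisible(x)
}

#' Best posterior draw refined by Nelder-Mead
#'
#' Convenience wrapper implementing the MCMC-then-NM training pipeline: take
#' the highest-posterior draw of a DREAM run and refine it with
#' \code{\link{map_estimate}} warm starts.
#'
#' @param post A \code{"posterior"} object.
#' @inheritParams map_estimate
#' @return A \code{"map_result"}.
#' @export
refine_map <- function(post, n_restarts = 5, seed = 1, maxit = 2000,
                       config = sim_config()) {
  stopifnot(inherits(post, "posterior"))
  best <- post$subsample[which.max(post$subsample_log_posterior), ]
  map_estimate(post$targets, prior = post$prior, free = post$free,
               fixed = post$fixed, n_restarts = n_restarts, seed = seed,
               init = best, maxit = maxit, config = config)
}
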