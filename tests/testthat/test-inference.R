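test_that("log-likelihood matches its closed form on precomputed outputs", {
  d <- c(pap_systolic = 30, cardiac_output = 5, cvp = 6)
  # perfect fit, unit sigmas: -(m/2) log 2 pi
  ts <- target_set(d, sigmas = c(pap_systolic = 1, cardiac_output = 1,
                                 cvp = 1))
  p <- default_parameters("healthy")
  expect_equal(log_likelihood(p, ts, outputs = d), -(3 / 2) * log(2 * pi))
  # single target, unit residual
  ts1 <- target_set(c(cvp = 6), sigmas = c(cvp = 1))
  expect_equal(log_likelihood(p, ts1, outputs = c(cvp = 7)),
               -0.5 * log(2 * pi) - 0.5)
})

test_that("masking a target removes exactly its term from the likelihood", {
  set.seed(3)
  tok <- clinical_tokens()
  nm <- c("pap_systolic", "cvp", "cardiac_output", "lvef", "rvedp")
  d <- stats::setNames(runif(5, 5, 50), nm)
  sg <- stats::setNames(runif(5, 0.5, 3), nm)
  g <- d + rnorm(5)
  p <- default_parameters("healthy")
  full <- log_likelihood(p, target_set(d, sg), outputs = g)
  # brute-force term-by-term oracle
  term <- function(i) -0.5 * log(2 * pi) - log(sg[i]) -
    0.5 * ((d[i] - g[i]) / sg[i])^2
  expect_equal(full, sum(vapply(1:5, term, numeric(1))))
  for (j in 1:5) {
    sub <- log_likelihood(p, target_set(d[-j], sg[-j]), outputs = g)
    expect_equal(sub, unname(full - term(j)))
  }
})

test_that("multistart Nelder-Mead recovers a quadratic optimum", {
  # identity model, one target per parameter: optimum is the data itself
  d <- c(0.3, 0.6, 0.45)
  neg <- function(u) sum((u - d)^2 / 1e-6)
  set.seed(9)
  starts <- matrix(runif(15), 5, 3)
  fit <- cardiolpn:::nm_multistart(neg, starts, maxit = 2000,
                                   reltol = 1e-10)
  expect_lt(max(abs(fit$best - d)), 1e-3 * 1e-3)  # within 1e-3 sigma
  # best value is non-increasing in restart count
  expect_true(all(diff(fit$trace) <= 0))
})

test_that("map_estimate is deterministic for a fixed seed", {
  ts <- validation_targets("healthy")
  warm <- default_parameters("healthy")
  a <- map_estimate(ts, n_restarts = 2, seed = 4, init = warm, maxit = 60)
  b <- map_estimate(ts, n_restarts = 2, seed = 4, init = warm, maxit = 60)
  expect_identical(a$params, b$params)
  expect_equal(a$log_posterior, b$log_posterior)
})

test_that("Gelman-Rubin matches hand-computed values", {
  # two 3-sample chains: W = 1, B = 150, Rhat = sqrt(50.667)
  expect_equal(gelman_rubin(cbind(c(0, 1, 2), c(10, 11, 12))),
               sqrt((2 / 3 + 150 / 3) / 1), tolerance = 1e-12)
  # identical chains: B = 0, Rhat = sqrt((n-1)/n)
  x <- rnorm(40)
  expect_equal(unname(gelman_rubin(cbind(x, x))), sqrt(39 / 40))
  # one long stream split in half converges to 1
  set.seed(7)
  y <- rnorm(20000)
  expect_lt(abs(gelman_rubin(matrix(y, ncol = 2)) - 1), 0.01)
  expect_error(gelman_rubin(cbind(rep(1, 10), rep(1, 10))),
               "within-chain variance")
})

test_that("DREAM samples a separable Gaussian toy posterior correctly", {
  mu <- c(0.5, 0.35, 0.6, 0.45); sg <- 0.05
  lp <- function(u) {
    if (any(u < 0 | u > 1)) return(-Inf)
    sum(dnorm(u, mu, sg, log = TRUE))
  }
  set.seed(31)
  core <- cardiolpn:::dream_core(lp, matrix(runif(40), 10, 4), 800)
  s <- apply(core$chains, 3, as.vector)
  nessm <- sqrt(ncol(s))  # crude; chains are correlated, allow 3 MCse
  for (j in 1:4) {
    mcse <- sd(s[, j]) / sqrt(nrow(s) / 20)  # conservative ESS guess
    expect_lt(abs(mean(s[, j]) - mu[j]), 3 * pmax(mcse, 1e-3))
    expect_lt(abs(var(s[, j]) / sg^2 - 1), 0.25)
  }
})

test_that("prior-only DREAM sampling recovers the uniform marginals", {
  lp <- function(u) if (any(u < 0 | u > 1)) -Inf else 0
  set.seed(13)
  core <- cardiolpn:::dream_core(lp, matrix(runif(30), 10, 3), 700)
  s <- apply(core$chains, 3, as.vector)
  for (j in 1:3) {
    ks <- suppressWarnings(ks.test(unique(s[, j]), "punif"))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("identical chains with zero proposal noise give the degenerate R-hat", {
  n <- 50
  x <- matrix(rep(rnorm(n), 3), n, 3)
  expect_equal(unname(gelman_rubin(x)), sqrt((n - 1) / n))
})

test_that("dream_sample runs end-to-end on a tiny problem and is seeded", {
  ts <- target_set(c(heart_rate2 = 80, systolic_bp_2 = 120,
                     diastolic_bp_2 = 80))
  post <- dream_sample(ts, n_chains = 4, n_iter = 40, seed = 2,
                       init = default_parameters("healthy"),
                       n_subsample = 50)
  expect_s3_class(post, "posterior")
  expect_equal(dim(post$chains)[2], 4)
  expect_equal(nrow(post$subsample), 50)
  expect_true(all(post$subsample[, "R_ra_rv"] ==
                    default_parameters("healthy")[["R_ra_rv"]]))
  post2 <- dream_sample(ts, n_chains = 4, n_iter = 40, seed = 2,
                        init = default_parameters("healthy"),
                        n_subsample = 50)
  expect_identical(post$subsample, post2$subsample)
})
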