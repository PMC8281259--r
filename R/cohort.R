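#' Validation target sets for three heart-failure severities
#'
#' Thirteen named clinical quantities (heart rate, right atrial pressure,
#' systolic/diastolic pulmonary pressure, wedge pressure, systemic pressures,
#' systemic vascular resistance, cardiac output, right/left ventricular
#' systolic and end-diastolic pressures) with severity-specific means and a
#' shared per-quantity standard deviation, shipped as a plain-text fixture.
#' The moderate column is, by construction, the linear midpoint of the
#' severe and healthy columns; \code{interpolate = TRUE} recomputes it that
#' way instead of reading the stored values.
#'
#' @param severity One of \code{"healthy"}, \code{"moderate"},
#'   \code{"severe"}.
#' @param interpolate Recompute the moderate column as the severe/healthy
#'   midpoint (only meaningful for \code{severity = "moderate"}).
#' @return A \code{\link{target_set}} named by extraction quantities.
#' @export
validation_targets <- function(severity = c("healthy", "moderate", "severe"),
                               interpolate = FALSE) {
  severity <- match.arg(severity)
  tab <- validation_table()
  vals <- if (severity == "moderate" && interpolate)
    (tab$severe + tab$healthy) / 2 else tab[[severity]]
  target_set(stats::setNames(vals, tab$token),
             stats::setNames(tab$sigma, tab$token))
}

#' The shipped validation table
#' @return Data frame with columns \code{qty}, \code{token}, \code{units},
#'   \code{severe}, \code{moderate}, \code{healthy}, \code{sigma}.
#' @export
validation_table <- function() {
  read.csv(system.file("extdata", "table2_validation.csv",
                       package = "cardiolpn"), stringsAsFactors = FALSE)
}

#' Read and write cohort tables
#'
#' A cohort table is a CSV with one row per patient and one column per
#' clinical token (blank cells = missing). An optional leading \code{id}
#' column is preserved.
#'
#' @param path CSV file path.
#' @return \code{load_cohort} returns a data frame whose clinical columns
#'   are numeric and \code{NA} where missing.
#' @rdname cohort_io
#' @export
load_cohort <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  tok <- clinical_tokens()$token
  cols <- setdiff(names(x), "id")
  bad <- setdiff(cols, tok)
  if (length(bad))
    stop("unknown clinical tokens in cohort file: ",
         paste(bad, collapse = ", "), call. = FALSE)
  for (cc in cols) {
    v <- x[[cc]]
    if (is.character(v)) v[v == ""] <- NA
    vn <- suppressWarnings(as.numeric(v))
    fail <- which(!is.na(v) & is.na(vn))
    if (length(fail))
      stop("non-numeric cell in column '", cc, "', row ", fail[1],
           call. = FALSE)
    x[[cc]] <- vn
  }
  x
}

#' @param cohort Data frame as returned by \code{load_cohort} or
#'   \code{\link{generate_cohort}}'s \code{$observed}.
#' @rdname cohort_io
#' @export
save_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Generate a synthetic patient cohort
#'
#' Draws ground-truth parameter vectors by interpolating between the
#' calibrated healthy and severe anchor parameter sets with per-parameter
#' jitter, simulates each patient, extracts the clinical targets, adds
#' zero-mean Gaussian noise with the dictionary standard deviations, and
#' applies a missingness pattern with modes at 4, 8 and 17 available targets
#' (heart rate and systemic pressures always observed). Non-physical noisy
#' values (negative pressures or volumes) are resampled. The ground-truth
#' pulmonary-hypertension label is derived from the noiseless pulmonary
#' values.
#'
#' @param n Number of patients.
#' @param severity_mix Probabilities of drawing a patient near the healthy,
#'   moderate and severe anchors (sums to 1).
#' @param mode_weights Probabilities of the 4-, 8- and 17-target
#'   availability modes.
#' @param jitter Relative half-width of the per-parameter uniform jitter.
#' @param noise Scale factor on the dictionary sigmas (0 = noiseless).
#' @param seed Integer seed.
#' @param config Simulation configuration.
#' @return A list of class \code{"synthetic_cohort"} with elements
#'   \code{observed} (patients x tokens data frame with \code{NA} for
#'   missing), \code{noiseless} (complete matrix), \code{params} (patients x
#'   45), \code{labels} (\code{"PH"}/\code{"non-PH"}), \code{severity}.
#' @export
generate_cohort <- function(n, severity_mix = c(0.4, 0.3, 0.3),
                            mode_weights = c(0.35, 0.35, 0.3),
                            jitter = 0.05, noise = 1, seed = 1,
                            config = sim_config()) {
  stopifnot(n >= 1, length(severity_mix) == 3,
            abs(sum(severity_mix) - 1) < 1e-8, length(mode_weights) == 3)
  set.seed(seed)
  ph <- default_parameters("healthy")
  ps <- default_parameters("severe")
  prior <- default_prior()
  tok <- clinical_tokens()
  tokens <- setdiff(tok$token, "lvot_max_flow")
  sig <- stats::setNames(tok$sigma, tok$token)[tokens]
  core <- c("heart_rate2", "systolic_bp_2", "diastolic_bp_2")
  modes <- c(4, 8, 17)
  pos_tokens <- tokens[!tokens %in%
                         c("mv_e_a_ratio")]  # strictly positive quantities

  params <- matrix(NA_real_, n, 45,
                   dimnames = list(NULL, parameter_names()))
  noiseless <- observed <- matrix(NA_real_, n, length(tokens),
                                  dimnames = list(NULL, tokens))
  labels <- character(n); sev <- character(n)
  sev_levels <- c("healthy", "moderate", "severe")
  sev_s <- c(healthy = 0, moderate = 0.5, severe = 1)

  for (i in seq_len(n)) {
    ok <- FALSE
    for (attempt in 1:20) {
      s_lab <- sample(sev_levels, 1, prob = severity_mix)
      s <- sev_s[[s_lab]] + runif(1, -0.15, 0.15)
      s <- min(max(s, 0), 1)
      y <- ph + s * (ps - ph)
      y <- y * runif(45, 1 - jitter, 1 + jitter)
      y <- pmin(pmax(y, prior$lo), prior$hi)
      w <- tryCatch(suppressWarnings(simulate_model(y, config)),
                    cardiolpn_diverged = function(e) NULL)
      if (is.null(w) || !isTRUE(w$converged)) next
      g <- extract_targets(w)[tokens]
      if (any(is.na(g))) next
      ok <- TRUE
      break
    }
    if (!ok)
      stop("cohort generation aborted: anchor interpolation failed to ",
           "produce a converged simulation for patient ", i, call. = FALSE)
    params[i, ] <- y
    noiseless[i, ] <- g
    sev[i] <- s_lab
    # ground-truth PH from noiseless pulmonary values
    mpap_nl <- mpap_estimate(g[["pap_systolic"]], g[["pap_diastolic"]])
    labels[i] <- if (mpap_nl > 25 || g[["pap_systolic"]] > 35)
      "PH" else "non-PH"
    # additive Gaussian noise, resampled while non-physical
    obs <- g + noise * rnorm(length(g)) * sig
    if (noise > 0) {
      for (k in which(tokens %in% pos_tokens)) {
        tries <- 0
        while (obs[k] <= 0 && tries < 100) {
          obs[k] <- g[k] + noise * rnorm(1) * sig[k]
          tries <- tries + 1
        }
        if (obs[k] <= 0) obs[k] <- g[k]
      }
    }
    observed[i, ] <- obs
  }
  # missingness: pick a mode, keep the core plus a random complement
  avail <- matrix(FALSE, n, length(tokens),
                  dimnames = list(NULL, tokens))
  for (i in seq_len(n)) {
    k <- sample(modes, 1, prob = mode_weights)
    keep <- core
    extra <- setdiff(tokens, core)
    if (k > length(core))
      keep <- c(core, sample(extra, min(k - length(core), length(extra))))
    avail[i, keep] <- TRUE
  }
  obs_df <- as.data.frame(observed)
  obs_df[!avail] <- NA
  obs_df <- cbind(id = seq_len(n), obs_df)
  structure(list(observed = obs_df, noiseless = noiseless, params = params,
                 labels = labels, severity = sev, available = avail),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", nrow(x$params), "patients;",
      sum(x$labels == "PH"), "PH /", sum(x$labels == "non-PH"), "non-PH\n")
  cat("  severity mix:", paste(names(table(x$severity)),
                               table(x$severity), collapse = ", "), "\n")
  invisible(x)
}

#' Target set for one cohort patient
#'
#' @param cohort A data frame (as from \code{load_cohort}) or a
#'   \code{synthetic_cohort}.
#' @param i Patient row index.
#' @param drop_tokens Tokens to exclude (default \code{lvot_max_flow}).
#' @return A \code{\link{target_set}} of the patient's available targets.
#' @export
patient_targets <- function(cohort, i, drop_tokens = "lvot_max_flow") {
  df <- if (inherits(cohort, "synthetic_cohort")) cohort$observed else cohort
  row <- df[i, setdiff(names(df), c("id", drop_tokens)), drop = FALSE]
  v <- unlist(row)
  v <- v[!is.na(v)]
  if (!length(v)) stop("patient ", i, " has no available targets",
                       call. = FALSE)
  target_set(v)
}
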