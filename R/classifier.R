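#' Ground-truth pulmonary hypertension label
#'
#' A patient is labelled hypertensive when mean PAP exceeds 25 mmHg or
#' systolic PAP exceeds 35 mmHg (strict inequalities). Mean PAP is taken
#' directly if available, otherwise estimated as \code{(sPAP + 2 dPAP)/3}
#' when both systolic and diastolic values are recorded. Patients with
#' neither determinable quantity are labelled \code{"undefined"} and
#' excluded from training and testing.
#'
#' @param values Named numeric vector (tokens \code{pap_systolic},
#'   \code{pap_diastolic}, optionally \code{mpap}); missing entries NA.
#' @return \code{"PH"}, \code{"non-PH"} or \code{"undefined"}.
#' @export
ground_truth_label <- function(values) {
  g <- function(k) if (k %in% names(values)) values[[k]] else NA_real_
  spap <- g("pap_systolic"); dpap <- g("pap_diastolic"); mpap <- g("mpap")
  if (is.na(mpap) && !is.na(spap) && !is.na(dpap))
    mpap <- mpap_estimate(spap, dpap)
  if (is.na(mpap) && is.na(spap)) return("undefined")
  if ((!is.na(mpap) && mpap > 25) || (!is.na(spap) && spap > 35))
    "PH" else "non-PH"
}

#' Missing-data imputation for clinical feature matrices
#'
#' \describe{
#'   \item{complete_case}{keep only the four always-available columns
#'     (heart rate, systolic/diastolic blood pressure, cardiac output).}
#'   \item{zero}{fill missing cells with 0.}
#'   \item{max}{fill with the per-column maximum of observed cells.}
#'   \item{far}{fill with 10 times the per-column maximum.}
#'   \item{median}{fill with the per-column median of observed cells.}
#' }
#' Fill statistics can be learned on a training fold and applied to a test
#' fold via the returned \code{fill} attribute.
#'
#' @param X Numeric matrix or data frame with NAs.
#' @param method One of the five methods above.
#' @param fill Optional named vector of per-column fill values (from a
#'   previous call) to apply instead of recomputing.
#' @return Completed numeric matrix with attribute \code{"fill"} (named
#'   fill values; \code{NULL} for complete_case). Columns that are fully
#'   missing under max/far/median are dropped with a warning.
#' @export
impute <- function(X, method = c("complete_case", "zero", "max", "far",
                                 "median"), fill = NULL) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (method == "complete_case") {
    keep <- intersect(c("heart_rate2", "systolic_bp_2", "diastolic_bp_2",
                        "cardiac_output"), colnames(X))
    return(structure(X[, keep, drop = FALSE], fill = NULL))
  }
  if (is.null(fill)) {
    fill <- apply(X, 2, function(v) {
      obs <- v[!is.na(v)]
      if (!length(obs)) return(NA_real_)
      switch(method, zero = 0, max = max(obs), far = 10 * max(obs),
             median = median(obs))
    })
  }
  dead <- names(fill)[is.na(fill)]
  if (length(dead)) {
    warning("dropping fully missing columns: ",
            paste(dead, collapse = ", "), call. = FALSE)
    X <- X[, setdiff(colnames(X), dead), drop = FALSE]
    fill <- fill[colnames(X)]
  }
  for (j in colnames(X)) {
    v <- X[, j]
    v[is.na(v)] <- fill[[j]]
    X[, j] <- v
  }
  structure(X, fill = fill)
}

# squared Euclidean distances between rows of A and rows of B
row_dist2 <- function(A, B) {
  outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
}

#' Class-rebalancing methods for imbalanced training sets
#'
#' \describe{
#'   \item{ros}{random over-sampling of the minority class to parity.}
#'   \item{rus}{random under-sampling of the majority class to parity.}
#'   \item{cc}{cluster centroids: the majority class is replaced by the
#'     k-means centroids with k equal to the minority count.}
#'   \item{smote}{synthetic minority points \code{x + u (x_nn - x)},
#'     \code{u ~ U(0,1)}, drawn along segments to one of the k = 5 nearest
#'     minority neighbours, up to parity.}
#'   \item{tl}{removal of majority members of Tomek pairs (mutual nearest
#'     neighbours of opposite class).}
#'   \item{smt}{SMOTE followed by Tomek-link removal.}
#' }
#'
#' @param X Numeric feature matrix (no missing cells).
#' @param y Factor or character vector of two class labels.
#' @param method One of \code{"ros"}, \code{"rus"}, \code{"cc"},
#'   \code{"smote"}, \code{"tl"}, \code{"smt"}.
#' @param seed Integer seed.
#' @param k SMOTE neighbour count.
#' @return List with balanced \code{X} and \code{y}.
#' @export
balance <- function(X, y, method = c("ros", "rus", "cc", "smote", "tl",
                                     "smt"), seed = 1, k = 5) {
  method <- match.arg(method)
  X <- as.matrix(X); y <- as.character(y)
  tab <- table(y)
  if (length(tab) != 2) stop("need exactly two classes", call. = FALSE)
  set.seed(seed)
  minc <- names(tab)[which.min(tab)]
  majc <- setdiff(names(tab), minc)
  imin <- which(y == minc); imaj <- which(y == majc)
  if (method == "ros") {
    extra <- sample(imin, length(imaj) - length(imin), replace = TRUE)
    idx <- c(seq_along(y), extra)
    return(list(X = X[idx, , drop = FALSE], y = y[idx]))
  }
  if (method == "rus") {
    keep <- c(imin, sample(imaj, length(imin)))
    return(list(X = X[keep, , drop = FALSE], y = y[keep]))
  }
  if (method == "cc") {
    km <- kmeans(X[imaj, , drop = FALSE],
                 centers = min(length(imin), length(imaj) - 1),
                 nstart = 5)
    Xb <- rbind(X[imin, , drop = FALSE], km$centers)
    return(list(X = Xb, y = c(y[imin], rep(majc, nrow(km$centers)))))
  }
  smote_points <- function() {
    if (length(imin) < 2) stop("SMOTE needs at least 2 minority samples",
                               call. = FALSE)
    need <- length(imaj) - length(imin)
    if (need <= 0) return(NULL)
    Xm <- X[imin, , drop = FALSE]
    D <- row_dist2(Xm, Xm); diag(D) <- Inf
    kk <- min(k, length(imin) - 1)
    nn <- t(apply(D, 1, function(r) order(r)[seq_len(kk)]))
    base <- sample(seq_along(imin), need, replace = TRUE)
    t(vapply(base, function(b) {
      nb <- nn[b, sample.int(kk, 1)]
      u <- runif(1)
      Xm[b, ] + u * (Xm[nb, ] - Xm[b, ])
    }, numeric(ncol(X))))
  }
  tomek_filter <- function(X, y) {
    D <- row_dist2(X, X); diag(D) <- Inf
    nn <- apply(D, 1, which.min)
    tab2 <- table(y)
    mj <- names(tab2)[which.max(tab2)]
    drop <- which(vapply(seq_along(y), function(i) {
      j <- nn[i]
      nn[j] == i && y[i] != y[j] && y[i] == mj
    }, logical(1)))
    if (length(drop)) list(X = X[-drop, , drop = FALSE], y = y[-drop])
    else list(X = X, y = y)
  }
  if (method == "smote") {
    S <- smote_points()
    return(list(X = rbind(X, S), y = c(y, rep(minc, NROW(S)))))
  }
  if (method == "tl") return(tomek_filter(X, y))
  # smt
  S <- smote_points()
  tomek_filter(rbind(X, S), c(y, rep(minc, NROW(S))))
}

#' Gaussian naive-Bayes classifier
#'
#' Class-conditional independent Gaussians per feature with class priors
#' equal to training frequencies; per-feature variances are floored at
#' \code{1e-9} times the largest feature variance to keep constant or
#' near-constant (e.g. imputed) columns well-defined.
#'
#' @param X Training feature matrix (no missing cells).
#' @param y Two (or more) class labels; at least 2 rows per class.
#' @return An object of class \code{"nb_model"}.
#' @export
nb_fit <- function(X, y) {
  X <- as.matrix(X); y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("single-class training set", call. = FALSE)
  if (any(table(y) < 2)) stop("need >= 2 training rows per class",
                              call. = FALSE)
  mu <- do.call(rbind, lapply(classes, function(cl)
    colMeans(X[y == cl, , drop = FALSE])))
  v <- do.call(rbind, lapply(classes, function(cl)
    apply(X[y == cl, , drop = FALSE], 2, var)))
  floorv <- 1e-9 * max(c(v, apply(X, 2, var)), na.rm = TRUE)
  if (!is.finite(floorv) || floorv <= 0) floorv <- 1e-9
  v <- pmax(v, floorv)
  structure(list(classes = classes, prior = as.vector(table(y)[classes]) /
                   length(y), mu = mu, var = v,
                 features = colnames(X)),
            class = "nb_model")
}

#' @param model An \code{"nb_model"}.
#' @param X Feature matrix to classify.
#' @rdname nb_fit
#' @return \code{nb_predict} returns a list with \code{labels} and a
#'   \code{prob} matrix (rows summing to one).
#' @export
nb_predict <- function(model, X) {
  X <- as.matrix(X)
  if (!is.null(model$features)) X <- X[, model$features, drop = FALSE]
  lp <- vapply(seq_along(model$classes), function(ci) {
    ld <- matrix(dnorm(X, rep(model$mu[ci, ], each = nrow(X)),
                       rep(sqrt(model$var[ci, ]), each = nrow(X)),
                       log = TRUE), nrow = nrow(X))
    log(model$prior[ci]) + rowSums(ld)
  }, numeric(nrow(X)))
  lp <- matrix(lp, nrow = nrow(X))
  m <- apply(lp, 1, max)
  pr <- exp(lp - m)
  pr <- pr / rowSums(pr)
  colnames(pr) <- model$classes
  list(labels = model$classes[max.col(pr, ties.method = "first")],
       prob = pr)
}

#' ROC curve and area under the curve
#'
#' @param score Numeric score (higher = more positive).
#' @param label Logical or 0/1 vector of true positives.
#' @return List with \code{fpr}, \code{tpr}, \code{auc}.
#' @export
roc_curve <- function(score, label) {
  label <- as.logical(label)
  ord <- order(score, decreasing = TRUE)
  lab <- label[ord]
  tpr <- c(0, cumsum(lab) / max(sum(lab), 1))
  fpr <- c(0, cumsum(!lab) / max(sum(!lab), 1))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' Evaluate a PH classifier with leakage-free preprocessing
#'
#' Stratified random 4/5-1/5 train/test split; imputation statistics are
#' learned on the training fold only and applied to the test fold;
#' class balancing is applied to the training fold only. Metrics are
#' computed on the untouched test fold.
#'
#' @param X Feature matrix (patients x features; may contain NAs).
#' @param y Labels (\code{"PH"}/\code{"non-PH"}); \code{"undefined"} rows
#'   are excluded.
#' @param imputation Imputation method (see \code{\link{impute}}) or
#'   \code{"none"} for complete feature sets.
#' @param balancing Balancing method (see \code{\link{balance}}) or
#'   \code{"none"}.
#' @param split Training fraction (default 4/5).
#' @param seed Integer seed for split and balancing.
#' @return List with \code{accuracy}, \code{confusion} (2x2 matrix),
#'   \code{roc}, \code{auc}, \code{recall} (per class), \code{test_idx}.
#' @export
evaluate_classifier <- function(X, y, imputation = "none",
                                balancing = "none", split = 4 / 5,
                                seed = 1) {
  X <- as.matrix(X); y <- as.character(y)
  keep <- y != "undefined"
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  if (length(y) < 5) stop("need at least 5 labelled patients",
                          call. = FALSE)
  set.seed(seed)
  idx_tr <- unlist(lapply(unique(y), function(cl) {
    i <- which(y == cl)
    sample(i, max(1, round(split * length(i))))
  }))
  idx_te <- setdiff(seq_along(y), idx_tr)
  if (length(unique(y[idx_te])) < 2)
    warning("test fold does not contain both classes", call. = FALSE)
  Xtr <- X[idx_tr, , drop = FALSE]; ytr <- y[idx_tr]
  Xte <- X[idx_te, , drop = FALSE]; yte <- y[idx_te]
  fill_used <- NULL
  if (imputation != "none") {
    Xtr <- impute(Xtr, imputation)
    fill_used <- attr(Xtr, "fill")
    Xte <- impute(Xte[, colnames(Xtr), drop = FALSE], imputation,
                  fill = fill_used)
  }
  if (balancing != "none") {
    bal <- balance(Xtr, ytr, balancing, seed = seed)
    Xtr <- bal$X; ytr <- bal$y
  }
  model <- nb_fit(Xtr, ytr)
  pred <- nb_predict(model, Xte)
  acc <- mean(pred$labels == yte)
  confusion <- table(factor(yte, levels = model$classes),
                     factor(pred$labels, levels = model$classes))
  rec <- diag(confusion) / pmax(rowSums(confusion), 1)
  ph_col <- if ("PH" %in% model$classes) "PH" else model$classes[1]
  roc <- roc_curve(pred$prob[, ph_col], yte == ph_col)
  list(accuracy = acc, confusion = confusion, roc = roc, auc = roc$auc,
       recall = rec, test_idx = idx_te, train_idx = idx_tr,
       fill = fill_used, model = model)
}
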