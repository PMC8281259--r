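test_that("ground-truth PH labelling uses strict thresholds and fallbacks", {
  expect_equal(ground_truth_label(c(pap_systolic = 36)), "PH")
  expect_equal(ground_truth_label(c(pap_systolic = 35, mpap = 25)),
               "non-PH")
  # mPAP estimated from s/d when absent: (60 + 2*20)/3 = 33.3 > 25
  expect_equal(ground_truth_label(c(pap_systolic = 33, pap_diastolic = 25)),
               "PH")
  expect_equal(ground_truth_label(c(pap_systolic = 30, pap_diastolic = 15)),
               "non-PH")
  expect_equal(ground_truth_label(c(cvp = 8)), "undefined")
  expect_equal(ground_truth_label(c(mpap = 26)), "PH")
})

test_that("imputation fills by the requested per-column statistic", {
  X <- cbind(heart_rate2 = c(60, 80, NA), systolic_bp_2 = c(110, NA, 130),
             cvp = c(1, NA, 3), lvef = c(NA, NA, NA))
  # complete matrix is unchanged by every fill method
  Xc <- X[, 1:3]; Xc[is.na(Xc)] <- 5
  for (m in c("zero", "max", "far", "median"))
    expect_equal(unclass(impute(Xc, m))[, ], Xc, ignore_attr = TRUE)
  expect_equal(unname(impute(X[, 1:3], "zero")[3, 1]), 0)
  expect_equal(unname(impute(X[, 1:3], "max")[2, 2]), 130)
  expect_equal(unname(impute(X[, 1:3], "far")[2, 3]), 30)
  expect_equal(unname(impute(cbind(v = c(1, NA, 3),
                                   heart_rate2 = 1:3), "median")[2, 1]), 2)
  expect_warning(impute(X, "median"), "fully missing")
  # complete-case keeps only the four always-available columns
  Xcc <- impute(cbind(X, cardiac_output = c(5, 4, 6),
                      diastolic_bp_2 = c(70, 75, 80)), "complete_case")
  expect_setequal(colnames(Xcc), c("heart_rate2", "systolic_bp_2",
                                   "diastolic_bp_2", "cardiac_output"))
  # stored fill values apply unchanged to new data
  tr <- impute(X[, 1:3], "median")
  te <- impute(cbind(heart_rate2 = NA_real_, systolic_bp_2 = NA_real_,
                     cvp = NA_real_), "median", fill = attr(tr, "fill"))
  expect_equal(unname(te[1, ]), unname(attr(tr, "fill")))
})

test_that("balancing methods equalize class counts as specified", {
  set.seed(10)
  X <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(80, 4), 40, 2))
  y <- c(rep("PH", 20), rep("non-PH", 40))
  for (m in c("ros", "rus", "cc", "smote")) {
    b <- balance(X, y, m, seed = 1)
    tab <- table(b$y)
    expect_equal(unname(tab[1]), unname(tab[2]), info = m)
    expect_equal(nrow(b$X), length(b$y))
  }
  # already balanced input passes through ros/rus (up to ordering)
  Xb <- X[c(1:20, 21:40), ]; yb <- y[c(1:20, 21:40)]
  for (m in c("ros", "rus")) {
    b <- balance(Xb, yb, m, seed = 1)
    expect_equal(sort(unname(c(table(b$y)))), sort(unname(c(table(yb)))))
  }
  expect_error(balance(X, rep("PH", 60), "ros"), "two classes")
  expect_error(balance(X[c(1, 21:40), ], y[c(1, 21:40)], "smote"),
               "at least 2 minority")
})

test_that("SMOTE points lie on segments between minority neighbours", {
  set.seed(11)
  Xm <- matrix(runif(10), 5, 2)
  X <- rbind(Xm, matrix(runif(30) + 2, 15, 2))
  y <- c(rep("a", 5), rep("b", 15))
  b <- balance(X, y, "smote", seed = 2)
  synth <- b$X[(nrow(X) + 1):nrow(b$X), , drop = FALSE]
  for (i in seq_len(nrow(synth))) {
    s <- synth[i, ]
    on_segment <- FALSE
    for (a in 1:5) for (c in 1:5) {
      if (a == c) next
      v <- Xm[c, ] - Xm[a, ]
      u <- if (sum(v^2) > 0) sum((s - Xm[a, ]) * v) / sum(v^2) else 0
      pt <- Xm[a, ] + u * v
      if (u >= -1e-8 && u <= 1 + 1e-8 &&
          sqrt(sum((s - pt)^2)) < 1e-8) on_segment <- TRUE
    }
    expect_true(on_segment)
  }
})

test_that("Tomek-link removal drops only majority members of mutual pairs", {
  X <- rbind(c(0, 0), c(0.1, 0), c(5, 5), c(9, 9))
  y <- c("min", "maj", "maj", "maj")
  b <- balance(X, y, "tl", seed = 1)
  expect_false(any(b$X[, 1] == 0.1))      # the paired majority point
  expect_true(any(b$y == "min"))
})

test_that("Gaussian naive Bayes separates well-separated classes", {
  set.seed(12)
  X <- matrix(c(rnorm(200, 0), rnorm(200, 10)), ncol = 1)
  y <- rep(c("a", "b"), each = 200)
  m <- nb_fit(X, y)
  pr <- nb_predict(m, X)
  expect_gte(mean(pr$labels == y), 0.99)
  expect_equal(unname(rowSums(pr$prob)), rep(1, 400))
  # equal likelihoods fall back to the larger prior
  m2 <- nb_fit(matrix(c(0, 0, 0, 0, 0, 0.0), 6, 1),
               c("a", "a", "a", "a", "b", "b"))
  p2 <- nb_predict(m2, matrix(0, 1, 1))
  expect_equal(p2$labels, "a")
  expect_error(nb_fit(X, rep("a", 400)), "single-class")
})

test_that("naive Bayes agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(14)
  X <- matrix(rnorm(300), 100, 3,
              dimnames = list(NULL, c("f1", "f2", "f3")))
  y <- ifelse(X[, 1] + 0.5 * X[, 2] + rnorm(100, 0, 0.5) > 0, "PH",
              "non-PH")
  m <- nb_fit(X, y)
  ref <- e1071::naiveBayes(as.data.frame(X), factor(y))
  pref <- predict(ref, as.data.frame(X), type = "raw")
  pown <- nb_predict(m, X)$prob
  expect_equal(unname(pown[, "PH"]), unname(pref[, "PH"]),
               tolerance = 1e-6)
})

test_that("classifier evaluation is leakage-free and exact on separable data", {
  set.seed(15)
  n <- 60
  X <- rbind(matrix(rnorm(2 * n / 3 * 2, 0), ncol = 2),
             matrix(rnorm(n / 3 * 2, 8), ncol = 2))
  colnames(X) <- c("f1", "f2")
  y <- c(rep("non-PH", 2 * n / 3), rep("PH", n / 3))
  for (m in c("none", "ros", "rus", "cc", "smote", "tl", "smt")) {
    res <- evaluate_classifier(X, y, balancing = m, seed = 3)
    expect_equal(res$accuracy, 1, info = m)
    expect_equal(sum(res$confusion), length(res$test_idx))
  }
  # leakage guard: imputation fill values must come from the training fold
  Xm <- X; Xm[2, 1] <- NA
  res <- evaluate_classifier(Xm, y, imputation = "max", seed = 3)
  tr_max <- max(Xm[res$train_idx, 1], na.rm = TRUE)
  full_max <- max(Xm[, 1], na.rm = TRUE)
  expect_equal(unname(res$fill[["f1"]]), tr_max)
  if (!full_max %in% Xm[res$train_idx, 1])
    expect_false(isTRUE(all.equal(res$fill[["f1"]], full_max)))
})

test_that("label-permuted cohorts score near the majority rate", {
  set.seed(16)
  n <- 90
  X <- matrix(rnorm(2 * n), ncol = 2,
              dimnames = list(NULL, c("f1", "f2")))
  acc <- replicate(50, {
    y <- sample(c(rep("PH", n / 3), rep("non-PH", 2 * n / 3)))
    evaluate_classifier(X, y, seed = sample.int(1e6, 1))$accuracy
  })
  # mean accuracy within binomial error of the majority rate 2/3
  expect_lt(abs(mean(acc) - 2 / 3), 3 * sqrt(2 / 9 / (50 * n / 5)) + 0.08)
})

test_that("balancing improves minority recall on an imbalanced cohort", {
  set.seed(17)
  rec <- vapply(1:20, function(s) {
    n1 <- 20; n0 <- 40
    X <- rbind(matrix(rnorm(n0 * 2, 0, 1.6), ncol = 2),
               matrix(rnorm(n1 * 2, 2.0, 1.6), ncol = 2))
    colnames(X) <- c("f1", "f2")
    y <- c(rep("non-PH", n0), rep("PH", n1))
    r0 <- evaluate_classifier(X, y, balancing = "none", seed = s)
    r1 <- evaluate_classifier(X, y, balancing = "ros", seed = s)
    c(r0$recall[["PH"]], r1$recall[["PH"]])
  }, numeric(2))
  expect_gte(mean(rec[2, ]), mean(rec[1, ]))
})
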