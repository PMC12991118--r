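## Small hand-wired masks/ps/tuning fixture: 6 neurons, 2 groups.
make_reg_fixture <- function() {
  target <- cbind(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
                  c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
  nontarget <- cbind(c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
                     c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE))
  masks <- structure(list(target = target, nontarget = nontarget),
                     class = "neuron_masks")
  w_ps <- matrix(c(2, 1, NA, 0.5, NA, NA,
                   NA, NA, 1.5, NA, NA, NA), 6)
  ps <- structure(list(w_ps = w_ps, mu = w_ps, sigma = w_ps * 0 + 1,
                       n_rep = matrix(20, 6, 2), min_repeats = 10),
                  class = "ps_response")
  set.seed(77)
  tun <- data.frame(neuron_id = 1:6,
                    pre = rnorm(6), early = rnorm(6), late = rnorm(6),
                    rew = rnorm(6), d_pre = rnorm(6), d_early = rnorm(6),
                    d_late = rnorm(6), d_rew = rnorm(6))
  list(masks = masks, ps = ps, tuning = tun)
}

test_that("pairwise correlations match direct covariance computation", {
  set.seed(2)
  dff <- matrix(rnorm(300), 3)
  ses <- toy_session(dff, trial_events(1, 2))
  C <- pairwise_correlations(ses)
  # direct covariance-ratio oracle
  for (i in 1:3) for (j in 1:3)
    expect_equal(C[i, j], cov(dff[i, ], dff[j, ]) /
                   sqrt(var(dff[i, ]) * var(dff[j, ])))
  expect_equal(diag(C), rep(1, 3))

  twin <- toy_session(rbind(dff[1, ], dff[1, ], -dff[1, ]), trial_events(1, 2))
  C2 <- pairwise_correlations(twin)
  expect_equal(C2[1, 2], 1)
  expect_equal(C2[1, 3], -1)

  flat <- toy_session(rbind(dff[1, ], rep(0.2, 100)), trial_events(1, 2))
  expect_warning(C3 <- pairwise_correlations(flat), "constant")
  expect_true(all(is.na(C3[2, ])))
})

test_that("correlation regressor is the response-weighted correlation sum", {
  fx <- make_reg_fixture()
  n <- 6
  C <- diag(n); C[lower.tri(C)] <- 0.5; C[upper.tri(C)] <- 0.5
  A <- correlation_regressor(C, fx$ps, fx$masks)
  # group 1 targets: neurons 1 (w=2), 2 (w=1); non-target 4 with C=0.5 to both
  expect_equal(A[4, 1], 0.5 * 2 + 0.5 * 1)
  # uncorrelated non-target -> 0
  C0 <- diag(n)
  expect_equal(correlation_regressor(C0, fx$ps, fx$masks)[4, 1], 0)
  # zero target responses -> 0 regardless of correlation
  ps0 <- fx$ps; ps0$w_ps[] <- 0
  expect_equal(correlation_regressor(C, ps0, fx$masks)[4, 1], 0)
  # entries undefined off the non-target mask
  expect_true(is.na(A[1, 1]))

  # one target, C = 0.5, weight 2 -> 1.0
  m1 <- structure(list(target = cbind(c(TRUE, FALSE)),
                       nontarget = cbind(c(FALSE, TRUE))),
                  class = "neuron_masks")
  p1 <- structure(list(w_ps = cbind(c(2, NA))), class = "ps_response")
  expect_equal(correlation_regressor(rbind(c(1, 0.5), c(0.5, 1)), p1, m1)[2, 1],
               1.0)
})

test_that("delta correlation regressor is antisymmetric and matches arithmetic", {
  fx <- make_reg_fixture()
  n <- 6
  set.seed(3)
  Ca <- stats::cov2cor(crossprod(matrix(rnorm(n * n), n)))
  Cb <- stats::cov2cor(crossprod(matrix(rnorm(n * n), n)))
  ps_b <- fx$ps; ps_b$w_ps <- fx$ps$w_ps * 1.3
  dA <- delta_correlation_regressor(Ca, Cb, fx$ps, ps_b, fx$masks)
  # identical days -> 0
  same <- delta_correlation_regressor(Ca, Ca, fx$ps, fx$ps, fx$masks)
  expect_true(all(abs(same[is.finite(same)]) < 1e-12))
  # swap flips sign
  swap <- delta_correlation_regressor(Cb, Ca, ps_b, fx$ps, fx$masks)
  expect_equal(dA, -swap)
  # hand case with the two targets of group 1, evaluated at non-target 4
  hand <- (Cb[4, 1] * 2 * 1.3 + Cb[4, 2] * 1 * 1.3) -
    (Ca[4, 1] * 2 + Ca[4, 2] * 1)
  expect_equal(dA[4, 1], hand)
})

test_that("regressor table has 24 (base4) or 80 (full8) tuning columns", {
  fx <- make_reg_fixture()
  t4 <- build_tuning_regressors(fx$tuning, fx$ps, fx$masks, "base4")
  expect_length(attr(t4, "tuning_cols"), 24L)
  expect_true("control" %in% names(t4))
  t8 <- build_tuning_regressors(fx$tuning, fx$ps, fx$masks, "full8")
  expect_length(attr(t8, "tuning_cols"), 80L)

  # like-to-like column: Rew_i * sum_j Rew_j W[j, g] (targets 1, 2 of group 1)
  tun <- fx$tuning
  row <- t4[t4$i == 4 & t4$g == 1, ]
  expect_equal(row[["nt_rew.tg_rew"]],
               tun$rew[4] * (tun$rew[1] * 2 + tun$rew[2] * 1))
  # X = 1 column is the plain summed target response times Y_i
  expect_equal(row[["nt_late.tg_1"]], tun$late[4] * 3)
  # control column equals the summed target response
  expect_equal(row$control, 3)
  # rows cover exactly the non-target pairs
  expect_equal(nrow(t4), sum(fx$masks$nontarget))
})

test_that("lasso recovers a planted single-column signal and its limits", {
  set.seed(14)
  n <- 400; p <- 10
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("c", 1:p)))
  y <- 2 * X[, 3] + rnorm(n, 0, 0.3)
  fit <- fit_lasso_cv(y, X, folds = 10, seed = 5)
  b <- coef(fit)
  expect_gt(b["c3"], 1)
  expect_true(all(abs(b[-3]) < 0.2))
  expect_gt(fit$holdout_cor, 0.9)

  # penalty -> infinity: all slopes zero, intercept = mean(y)
  top <- fit_lasso_cv(y, X, lambda = 1e6)
  expect_true(all(top$coefficients == 0))
  expect_equal(top$intercept, mean(y))

  # penalty -> 0 equals OLS (normal-equations oracle) on a full-rank case
  X2 <- X[, 1:3]; y2 <- X2 %*% c(1, -2, 0.5) + rnorm(n, 0, 0.1)
  small <- fit_lasso_cv(y2, X2, lambda = 1e-8)
  Xs <- scale(X2)
  ols <- solve(crossprod(cbind(1, Xs)), crossprod(cbind(1, Xs), y2))
  expect_equal(unname(small$coefficients), ols[2:4], tolerance = 1e-4)

  # raw-scale back-transform
  expect_equal(coef(small, "raw"),
               small$coefficients / apply(X2, 2, sd))
})

test_that("out-of-fold partition is a disjoint cover and fold_by groups stay together", {
  set.seed(9)
  X <- matrix(rnorm(600), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rnorm(200)
  fit <- fit_lasso_cv(y, X, folds = 10, seed = 3)
  expect_equal(sort(unique(fit$foldid)), 1:10)
  expect_length(fit$foldid, 200)
  expect_true(all(is.finite(fit$oof_pred)))

  sess <- rep(1:20, each = 10)
  fit2 <- fit_lasso_cv(y, X, folds = 5, seed = 3, fold_by = sess)
  expect_true(all(tapply(fit2$foldid, sess, function(f) length(unique(f))) == 1))
  expect_error(fit_lasso_cv(y[1:5], X[1:5, ], folds = 10), "fewer rows")
})

test_that("positive Wald test is calibrated under the null and powered", {
  set.seed(6)
  ps <- replicate(200, {
    y <- rnorm(60); f <- rnorm(60); ctrl <- rnorm(60)
    wald_positive_test(y, f, ctrl)$p_value
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)

  hits <- vapply(1:20, function(s) {
    set.seed(s)
    f <- rnorm(1000)
    y <- f + rnorm(1000, 0, 0.5)
    wald_positive_test(y, f)$p_value < 1e-4
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # sign-flipped focal: p above 0.5
  set.seed(7)
  f <- rnorm(500); y <- f + rnorm(500, 0, 0.5)
  expect_gt(wald_positive_test(y, -f)$p_value, 0.5)

  # collinear focal/control is rejected with a condition number
  expect_error(wald_positive_test(y, f, f), "collinear")
})

test_that("single-regressor scan flags only the planted column", {
  fx <- make_reg_fixture()
  # synthetic table: 24 noise columns + control, with one planted signal
  set.seed(18)
  n <- 500
  cols <- as.data.frame(matrix(rnorm(n * 24), n))
  names(cols) <- paste0("t", 1:24)
  tab <- cbind(data.frame(i = 1:n, g = 1), cols,
               data.frame(control = rnorm(n)))
  attr(tab, "tuning_cols") <- names(cols)
  class(tab) <- c("regressor_table", "data.frame")

  y <- 0.8 * tab$t7 + 0.5 * tab$control + rnorm(n, 0, 0.5)
  scan <- single_regressor_scan(y, tab)
  expect_equal(scan$term, names(cols))           # ordering preserved
  sig <- scan$p_value < 0.05 / 24
  expect_true(sig[7])
  expect_equal(sum(sig[-7]), 0)

  # all-noise table: significant count near alpha * columns
  y0 <- rnorm(n)
  scan0 <- single_regressor_scan(y0, tab)
  expect_lte(sum(scan0$p_value < 0.05), 6)
})
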