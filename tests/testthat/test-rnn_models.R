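small_cfg <- function(n = 6, ...) {
  rnn_config(n = n, d = 3, noise_scale = 0, t_pre = 0.06, t_late = 0.06,
             stabilization_trials = 3, ...)
}

## loss of one deterministic trial, as optimized by train_bptt
trial_loss <- function(model) {
  fw <- photoplast:::rnn_trial_forward(model)
  mean((fw$H[model$cn, -seq_len(fw$Tp)] - model$gamma_hat)^2)
}

## central-difference gradient for one weight entry
num_grad <- function(model, field, i, j, eps = 1e-6) {
  mp <- model; mm <- model
  if (is.matrix(model[[field]])) {
    mp[[field]][i, j] <- mp[[field]][i, j] + eps
    mm[[field]][i, j] <- mm[[field]][i, j] - eps
  } else {
    mp[[field]][i] <- mp[[field]][i] + eps
    mm[[field]][i] <- mm[[field]][i] - eps
  }
  (trial_loss(mp) - trial_loss(mm)) / (2 * eps)
}

prep_model <- function(cfg, seed = 2) {
  m <- rnn_model(cfg, seed = seed)
  stab <- replicate(3, photoplast:::rnn_trial_forward(m), simplify = FALSE)
  m <- select_model_cn(m, stab)
  # make the target nontrivially different from current activity
  m$gamma_hat <- m$gamma_hat + 0.3
  m
}

test_that("zero-weight zero-input dynamics stay at the fixed point", {
  cfg <- small_cfg()
  m <- rnn_model(cfg, seed = 1)
  m$W_rec[] <- 0; m$W_inp[] <- 0
  h <- step_dynamics(m, rep(0, cfg$n), rep(0, cfg$d), deterministic = TRUE)
  expect_equal(h, rep(0, cfg$n))
  expect_error(step_dynamics(m, c(Inf, rep(0, 5)), rep(0, 3)), "non-finite")
})

test_that("linear dynamics match the closed-form matrix recursion", {
  cfg <- rnn_config(n = 2, d = 1, noise_scale = 0, nonlinearity = "linear")
  m <- rnn_model(cfg, seed = 3)
  a <- cfg$dt / cfg$tau
  A <- (1 - a) * diag(2) + a * m$W_rec
  bx <- a * m$W_inp %*% 1.5
  h <- c(0.2, -0.1)
  h_oracle <- h
  for (k in 1:50) {
    h <- step_dynamics(m, h, 1.5, deterministic = TRUE)
    h_oracle <- as.numeric(A %*% h_oracle + bx)
  }
  expect_equal(h, h_oracle, tolerance = 1e-12)
})

test_that("trial simulation is deterministic given the seed", {
  cfg <- rnn_config(n = 20, d = 4, t_pre = 0.2, t_late = 0.2,
                    stabilization_trials = 2)
  m <- rnn_model(cfg, seed = 5)
  set.seed(9); f1 <- photoplast:::rnn_trial_forward(m)
  set.seed(9); f2 <- photoplast:::rnn_trial_forward(m)
  expect_identical(f1$H, f2$H)
})

test_that("CN selection applies the eligibility and minimal-tuning criterion", {
  cfg <- small_cfg()
  m <- rnn_model(cfg, seed = 7)
  # synthetic stabilization log with known per-neuron means
  mk_stab <- function(pre, late, Tp = 5, Tl = 5) {
    H <- cbind(matrix(pre, length(pre), Tp), matrix(late, length(late), Tl))
    list(list(H = H, Tp = Tp, Tl = Tl))
  }
  pre <- c(0.9, 0.1, 0.5, 0.8, 0.05, 0.3)
  late <- c(0.5, 0.1, 0.45, 0.9, 0.05, 0.2)
  sel <- select_model_cn(m, mk_stab(pre, late))
  # brute-force oracle
  elig <- which(pre > median(pre) & late > median(late))
  expect_equal(sel$cn, elig[which.min(abs(pre - late)[elig])])
  # target is the 95th percentile of CN stabilization activity
  expect_equal(sel$gamma_hat,
               unname(quantile(c(rep(pre[sel$cn], 5), rep(late[sel$cn], 5)),
                               0.95)))
  # symmetric tie breaks to the lowest index
  pre2 <- c(0.8, 0.8, 0.1, 0.1); late2 <- c(0.8, 0.8, 0.1, 0.1)
  cfg4 <- rnn_config(n = 4, d = 2, noise_scale = 0)
  m4 <- rnn_model(cfg4, seed = 1)
  expect_equal(select_model_cn(m4, mk_stab(pre2, late2))$cn, 1L)
})

test_that("feedback vector satisfies w_back . w_bci = 1 exactly across seeds", {
  for (s in 1:12) {
    m <- prep_model(small_cfg(n = 16), seed = s)
    expect_identical(sum(m$w_back * m$w_bci), 1)
    expect_equal(sum(m$w_bci), 1)
  }
})

test_that("BPTT gradients match finite differences for every plasticity locus", {
  # align the credit-routing vector with the true readout: with
  # misalignment the update is deliberately not the loss gradient
  for (locus in c("recurrent", "input", "excitability")) {
    m <- prep_model(small_cfg(plasticity_locus = locus), seed = 11)
    m$w_back <- m$w_bci
    m$a_exc <- 1 + 0.1 * stats::rnorm(m$cfg$n)
    fw <- photoplast:::rnn_trial_forward(m)
    gr <- photoplast:::rnn_trial_backward(m, fw)
    field <- switch(locus, recurrent = "W_rec", input = "W_inp",
                    excitability = "a_exc")
    g_an <- switch(locus, recurrent = gr$dW, input = gr$dU,
                   excitability = gr$da)
    set.seed(13)
    for (k in 1:6) {
      i <- sample(nrow(as.matrix(g_an)), 1)
      j <- sample(ncol(as.matrix(g_an)), 1)
      g_num <- num_grad(m, field, i, j)
      g_a <- if (is.matrix(g_an)) g_an[i, j] else g_an[i]
      expect_equal(g_a, g_num, tolerance = 1e-4)
    }
  }
  # upstream variant: gradient w.r.t. the upstream recurrent weights
  mu <- prep_model(small_cfg(plasticity_locus = "upstream_recurrent",
                             upstream_n = 4), seed = 17)
  mu$w_back <- mu$w_bci
  fwu <- photoplast:::rnn_trial_forward(mu)
  gru <- photoplast:::rnn_trial_backward(mu, fwu)
  set.seed(19)
  for (k in 1:5) {
    i <- sample(4, 1); j <- sample(4, 1)
    expect_equal(gru$dWup[i, j], num_grad(mu, "W_rec_up", i, j),
                 tolerance = 1e-4)
  }
})

test_that("training modifies only the declared plasticity locus", {
  cfg <- rnn_config(n = 30, d = 5, t_pre = 0.3, t_late = 0.3,
                    stabilization_trials = 3)
  run <- function(locus) {
    c2 <- cfg; c2$plasticity_locus <- locus
    train_bptt(rnn_model(c2, seed = 21), trials = 5, lr = 0.5, seed = 4)
  }
  tr_rec <- run("recurrent")
  expect_identical(tr_rec$model$W_inp, tr_rec$model_init$W_inp)
  expect_false(identical(tr_rec$model$W_rec, tr_rec$model_init$W_rec))

  tr_inp <- run("input")
  expect_identical(tr_inp$model$W_rec, tr_inp$model_init$W_rec)
  expect_false(identical(tr_inp$model$W_inp, tr_inp$model_init$W_inp))

  tr_exc <- run("excitability")
  expect_identical(tr_exc$model$W_rec, tr_exc$model_init$W_rec)
  expect_identical(tr_exc$model$W_inp, tr_exc$model_init$W_inp)
  expect_false(identical(tr_exc$model$a_exc, tr_exc$model_init$a_exc))

  # lr = 0: nothing changes at all
  tr0 <- train_bptt(rnn_model(cfg, seed = 21), trials = 5, lr = 0, seed = 4)
  expect_identical(tr0$model$W_rec, tr0$model_init$W_rec)
  expect_identical(tr0$model$W_inp, tr0$model_init$W_inp)
})

test_that("training is deterministic end-to-end without noise", {
  cfg <- rnn_config(n = 20, d = 4, noise_scale = 0, t_pre = 0.2,
                    t_late = 0.2, stabilization_trials = 2)
  t1 <- train_bptt(rnn_model(cfg, seed = 6), trials = 4, lr = 0.2, seed = 8)
  t2 <- train_bptt(rnn_model(cfg, seed = 6), trials = 4, lr = 0.2, seed = 8)
  expect_identical(t1$model$W_rec, t2$model$W_rec)
  expect_identical(t1$loss, t2$loss)
})

test_that("training reduces loss and raises CN late activity toward target", {
  cfg <- rnn_config(n = 60, d = 8, t_pre = 0.5, t_late = 0.5,
                    stabilization_trials = 5)
  tr <- train_bptt(rnn_model(cfg, seed = 23), trials = 30, lr = 0.3, seed = 2)
  expect_false(tr$rejected)
  expect_lt(min(tr$loss), tr$loss[1])
  expect_false(is.na(tr$trials_to_target))
})

test_that("decoupled networks show no off-target photostimulation response", {
  cfg <- rnn_config(n = 10, d = 3, noise_scale = 0.005)
  m <- rnn_model(cfg, seed = 31)
  m$W_rec[] <- 0
  W <- insilico_photostim(m, repeats = 5, seed = 3)
  off <- W[row(W) != col(W)]
  expect_lt(max(abs(off)), 0.02)
  # direct responses are large and positive (clamped to h_pert = 1)
  expect_true(all(diag(W) > 0.5))
  expect_error(insilico_photostim(m, neurons = 99), "out of range")
})

test_that("linear-network photostim matches the analytic propagator column", {
  cfg <- rnn_config(n = 5, d = 2, noise_scale = 0, nonlinearity = "linear",
                    ps_input_noise = 0, h_pert = 0.1)
  m <- rnn_model(cfg, seed = 37)
  W <- m$W_rec
  est <- insilico_photostim(m, repeats = 1, during_s = 10, during_skip_s = 5,
                            seed = 1)
  for (g in 1:5) {
    expected <- solve(diag(4) - W[-g, -g], W[-g, g] * cfg$h_pert)
    expect_equal(est[-g, g], expected, tolerance = 1e-3)
  }
})

test_that("averaging over more photostim repeats reduces estimate variance", {
  cfg <- rnn_config(n = 8, d = 3)
  m <- rnn_model(cfg, seed = 41)
  est <- function(repeats, seed)
    insilico_photostim(m, neurons = 1, repeats = repeats, seed = seed)[2, 1]
  v1 <- var(vapply(1:40, function(s) est(1, s), numeric(1)))
  v5 <- var(vapply(1:40, function(s) est(5, s), numeric(1)))
  expect_gt(v1, v5)
})

test_that("loop input ratio is zero without a loop and scales with W_csc", {
  cfg <- rnn_config(n = 6, d = 3, noise_scale = 0)
  m0 <- rnn_model(cfg, seed = 43)
  H <- matrix(rnorm(18), 6); X <- matrix(rnorm(9), 3)
  expect_equal(loop_input_ratio(m0, H, X), 0)

  cfg2 <- rnn_config(n = 6, d = 3, noise_scale = 0, w_csc_scale = 0.2)
  m <- rnn_model(cfg2, seed = 43)
  r1 <- loop_input_ratio(m, H, X)
  m2 <- m; m2$W_csc <- 2 * m$W_csc
  expect_equal(loop_input_ratio(m2, H, X), 2 * r1)

  # 3-step hand computation
  hand <- sum(sqrt(colSums((m$W_csc %*% H)^2))) / sum(sqrt(colSums(X^2)))
  expect_equal(r1, hand)
  expect_error(loop_input_ratio(m, H, X * 0), "zero norm")
})

test_that("rejection bookkeeping flags runs with no loss decrease", {
  cfg <- rnn_config(n = 20, d = 4, noise_scale = 0, t_pre = 0.2,
                    t_late = 0.2, stabilization_trials = 2)
  tr0 <- train_bptt(rnn_model(cfg, seed = 6), trials = 4, lr = 0, seed = 8)
  expect_true(tr0$rejected)   # frozen weights cannot reduce a noiseless loss
})

test_that("learning is robust to rescaling the trial-period durations by half", {
  for (scale in c(0.5, 1.5)) {
    cfg <- rnn_config(n = 50, d = 6, t_pre = scale, t_late = scale,
                      stabilization_trials = 4)
    tr <- train_bptt(rnn_model(cfg, seed = 29), trials = 25, lr = 0.1,
                     seed = 3)
    expect_false(tr$rejected)
    expect_false(is.na(tr$trials_to_target))
  }
})
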