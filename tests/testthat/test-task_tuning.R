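make_ramp_session <- function() {
  fr <- 20
  times <- seq(0, 60, by = 1 / fr)
  dff <- rbind(times / 60,                      # slow ramp
               0.5 + 0.3 * sin(2 * pi * times / 7),
               rep(0.2, length(times)))         # constant
  ev <- trial_events(start_s = c(5, 13, 26), reward_s = c(8, NA, 28.5))
  toy_session(dff, ev, cn = 1L, frame_rate = fr)
}

test_that("epoch means equal hand-computed window means with the availability rules", {
  ses <- make_ramp_session()
  ea <- epoch_activity(ses)
  times <- seq(0, 60, by = 1 / 20)
  wm <- function(i, a, b) mean(ses$dff[i, times > a & times <= b])

  # trial 1 (hit, start 5, reward 8): no preceding hit -> pretrial NA
  expect_true(all(is.na(ea$pre[, 1])))
  for (i in 1:3) {
    expect_equal(ea$early[i, 1], wm(i, 5, 7))
    expect_equal(ea$late[i, 1], wm(i, 7, 8))
    expect_equal(ea$rew[i, 1], wm(i, 8, 11))
  }
  # trial 2 (miss): pretrial available (previous trial hit), others NA
  expect_equal(ea$pre[2, 2], wm(2, 11, 12))
  expect_true(all(is.na(ea$early[, 2])))
  expect_true(all(is.na(ea$late[, 2])))
  expect_true(all(is.na(ea$rew[, 2])))
  # trial 3 (hit after a miss): pretrial NA again
  expect_true(all(is.na(ea$pre[, 3])))
  expect_equal(ea$late[1, 3], wm(1, 27.5, 28.5))

  # constant neuron: every available entry equals the constant
  avail <- c(ea$early[3, ], ea$late[3, ], ea$rew[3, ], ea$pre[3, ])
  expect_true(all(abs(avail[is.finite(avail)] - 0.2) < 1e-12))
})

test_that("short hit trials have no early entry and trials are capped at 40", {
  fr <- 20
  dff <- matrix(0.1, 1, 1201)
  ev <- trial_events(start_s = c(2, 10), reward_s = c(2.8, 11.5))
  ea <- epoch_activity(toy_session(dff, ev, frame_rate = fr))
  expect_true(is.na(ea$early[1, 1]))   # duration 0.8 s < 1 s
  expect_false(is.na(ea$early[1, 2]))

  many <- trial_events(start_s = seq(2, 2 + 49 * 12, by = 12),
                       reward_s = seq(5, 5 + 49 * 12, by = 12))
  dff2 <- matrix(0.1, 1, (2 + 49 * 12 + 10) * fr)
  ea2 <- epoch_activity(toy_session(dff2, many, frame_rate = fr))
  expect_equal(ncol(ea2$late), 40L)
})

test_that("tuning base is the trial mean and delta the OLS slope over trials", {
  # build an epoch_activity object directly
  mk <- function(vals) {
    m <- matrix(vals, nrow = 1)
    structure(list(pre = m, early = m, late = m, rew = m,
                   events = data.frame()), class = "epoch_activity")
  }
  flat <- tuning_and_delta(mk(c(1, 1, 1, 1)))
  expect_equal(flat$late, 1)
  expect_equal(flat$d_late, 0)

  unit <- tuning_and_delta(mk(1:4))
  expect_equal(unit$d_early, 1)

  # closed-form OLS slope oracle: cov(x,y)/var(x) = 0.16
  hand <- tuning_and_delta(mk(c(0.2, 0.1, 0.5, 0.6)))
  expect_equal(hand$d_rew, 0.16)

  single <- tuning_and_delta(mk(c(0.7, NA, NA, NA)))
  expect_equal(single$pre, 0.7)
  expect_true(is.na(single$d_pre))

  # delta invariant to adding a constant; base shifts by it
  shifted <- tuning_and_delta(mk(c(0.2, 0.1, 0.5, 0.6) + 3))
  expect_equal(shifted$d_rew, hand$d_rew)
  expect_equal(shifted$rew, hand$rew + 3)
})

test_that("CN sparsity bootstrap matches exhaustive enumeration and edge cases", {
  set.seed(5)
  deltas <- replicate(3, rnorm(10), simplify = FALSE)
  cns <- c(2L, 5L, 9L)
  bs <- cn_sparsity_bootstrap(deltas, cns, n_draws = 4000, seed = 99)
  # brute-force oracle: all 10^3 single-neuron draw combinations
  combos <- expand.grid(a = deltas[[1]], b = deltas[[2]], c = deltas[[3]])
  null_exact <- apply(as.matrix(combos), 1L, median)
  cn_med <- median(c(deltas[[1]][2], deltas[[2]][5], deltas[[3]][9]))
  pct_exact <- mean(null_exact < cn_med) + 0.5 * mean(null_exact == cn_med)
  expect_equal(bs$cn_median, cn_med)
  expect_lt(abs(bs$cn_median_percentile - pct_exact), 0.03)

  # CN above every other neuron in every session -> percentile 1, p below
  # 1/n_draws (null restricted to non-CN candidates)
  hi <- lapply(deltas, function(d) { d[1] <- max(d) + 10; d })
  not_cn <- lapply(hi, function(d) seq_along(d) != 1L)
  bs_hi <- cn_sparsity_bootstrap(hi, c(1L, 1L, 1L), n_draws = 1000, seed = 1,
                                 candidate_masks = not_cn)
  expect_equal(bs_hi$cn_median_percentile, 1)
  expect_lte(bs_hi$p_value, 1 / 1000)

  # exchangeable null: all neurons identical -> percentile 0.5, p = 1
  same <- replicate(3, rep(0.3, 8), simplify = FALSE)
  bs_same <- cn_sparsity_bootstrap(same, c(1L, 2L, 3L), n_draws = 500, seed = 2)
  expect_equal(bs_same$cn_median_percentile, 0.5)

  expect_error(cn_sparsity_bootstrap(deltas, cns, n_draws = 500),
               "seed")
  expect_error(cn_sparsity_bootstrap(deltas, cns, n_draws = 500, seed = 1,
                                     candidate_masks = list(rep(FALSE, 10),
                                                            rep(TRUE, 10),
                                                            rep(TRUE, 10))),
               "session 1")
})

test_that("bootstrap percentile of an exchangeable neuron is uniform", {
  # draw fresh iid slopes each repetition and score neuron 1 as if it were
  # the CN; its percentile must be uniform on [0,1]
  set.seed(31)
  pct <- replicate(60, {
    deltas <- replicate(4, rnorm(12), simplify = FALSE)
    cn_sparsity_bootstrap(deltas, rep(1L, 4), n_draws = 300,
                          seed = sample.int(1e6, 1))$cn_median_percentile
  })
  expect_gt(suppressWarnings(ks.test(pct, "punif")$p.value), 0.01)
})

test_that("candidate CN mask is the rank-space neighbourhood of the reference", {
  set.seed(8)
  fr <- 20
  n <- 100
  times <- seq(0, 30, by = 1 / fr)
  dff <- matrix(rnorm(n * length(times), 0, 0.1), n)
  dff[1:50, ] <- dff[1:50, ] + outer(seq(0, 2, length.out = 50),
                                     as.numeric(times > 10 & times < 20))
  dff[n, ] <- 0  # silent neuron
  ev <- trial_events(start_s = c(5, 15), reward_s = c(8, 18))
  ses <- toy_session(dff, ev, cn = 25L, frame_rate = fr)

  mask <- candidate_cn_mask(ses)
  expect_true(mask[25])                      # reference is its own neighbour
  expect_equal(sum(mask), 5L)                # top 5% of 100

  # rank-based oracle
  st <- photoplast:::cn_screen_stats(ses)
  r1 <- rank(st$modulation); r2 <- rank(st$start_tuning)
  d <- sqrt((r1 - r1[25])^2 + (r2 - r2[25])^2)
  expect_equal(mask, d <= sort(d)[5])

  # a silent neuron is far from an active, tuned reference
  expect_false(mask[n])
})

test_that("epoch-weighted average is a normalized weighted mean of traces", {
  ses <- make_ramp_session()
  tun <- tuning_and_delta(epoch_activity(ses))

  one <- tun; one$late <- c(1, 0, 0)
  expect_equal(epoch_weighted_average(ses, one, "late"), ses$dff[1, ])

  twin <- toy_session(rbind(ses$dff[2, ], ses$dff[2, ]), ses$events)
  t2 <- data.frame(late = c(1, 1))
  expect_equal(epoch_weighted_average(twin, t2, "late"), ses$dff[2, ])

  # 3-neuron hand-computed weighted mean with signed weights
  t3 <- data.frame(late = c(0.5, -1, 2))
  expect_equal(epoch_weighted_average(ses, t3, "late"),
               as.numeric(0.5 * ses$dff[1, ] - ses$dff[2, ] + 2 * ses$dff[3, ]) / 3.5)

  t0 <- data.frame(late = c(0, 0, 0))
  expect_error(epoch_weighted_average(ses, t0, "late"), "zero")
})

test_that("pretrial-performance regression detects a planted negative slope", {
  fr <- 20
  mk_session <- function(seed) {
    set.seed(seed)
    n_tr <- 30
    starts <- cumsum(rep(14, n_tr)) - 7
    pre_amp <- runif(n_tr, 0.1, 1)
    dur <- pmax(0.5, 5 - 3 * pre_amp + rnorm(n_tr, 0, 0.3))
    times <- seq(0, max(starts) + 12, by = 1 / fr)
    dff <- matrix(0.05, 4, length(times))
    for (I in seq_len(n_tr)) {
      sel <- times > starts[I] - 2 & times <= starts[I] - 1
      dff[, sel] <- pre_amp[I]
    }
    ev <- data.frame(start_s = starts, reward_s = starts + dur,
                     outcome = "hit", duration_s = dur)
    toy_session(dff, ev, frame_rate = fr)
  }
  ps <- vapply(1:8, function(s)
    pretrial_performance_regression(mk_session(s), max_trials = 30)$wald_p,
    numeric(1))
  expect_gte(mean(ps < 0.01), 0.95)

  # constant durations: slope 0
  ses <- make_ramp_session()
  ev <- trial_events(start_s = seq(5, 53, by = 4),
                     reward_s = seq(5, 53, by = 4) + 2)
  ses2 <- toy_session(rbind(sin(seq(0, 60, by = 0.05))^2 + 0.1), ev)
  out <- suppressWarnings(pretrial_performance_regression(ses2, max_trials = 40))
  expect_equal(out$slope, 0, tolerance = 1e-10)
})
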