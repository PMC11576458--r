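make_task_epochs_with_events <- function(seq, n_samples = 16, fs = 512) {
  lay <- mini_layout()
  dat <- array(rnorm(nrow(seq) * nrow(lay) * n_samples, sd = 1e-6),
               c(nrow(seq), nrow(lay), n_samples))
  make_epochs(dat, fs, 0, lay, seq$tone, events = seq)
}

test_that("trial selection applies the exclusions and equalizes counts", {
  sq <- oddball_sequence(n_standards = 612, n_deviants_per_type = 102, seed = 7)
  ep <- make_task_epochs_with_events(sq)
  sel <- select_trials(ep, seed = 1)
  kept <- sel$condition[sel$kept]
  expect_equal(sum(kept == "standard"), sum(kept == "deviant"))
  # independent oracle for the expected equalized count
  is_dev <- sq$tone != "standard"
  post_dev <- c(FALSE, head(is_dev, -1)) & sq$tone == "standard"
  eligible_std <- sum(sq$tone == "standard" & !sq$is_habituation & !post_dev)
  expected <- min(eligible_std, sum(is_dev))
  expect_equal(sum(kept == "deviant"), expected)
  expect_equal(expected, 204)  # full design: all 204 deviants retained
  # habituation and post-deviant standards never survive selection
  expect_false(any(sel$kept & sel$events$is_habituation))
  expect_false(any(sel$kept & sel$condition == "standard" & sel$events$follows_deviant))
})

test_that("selection is seed-deterministic and honours cross-system caps", {
  sq <- oddball_sequence(n_standards = 40, n_deviants_per_type = 6, seed = 3)
  ep <- make_task_epochs_with_events(sq)
  a <- select_trials(ep, seed = 9)
  b <- select_trials(ep, seed = 9)
  expect_identical(a$kept, b$kept)
  capped <- select_trials(ep, seed = 9, n_per_condition = 5)
  expect_equal(as.integer(table(capped$condition[capped$kept])), c(5L, 5L))
  one_cond <- ep
  one_cond$condition <- rep("standard", length(ep$condition))
  one_cond$events$tone <- "standard"
  expect_error(select_trials(one_cond, seed = 1), "no trials")
})

test_that("condition averaging subtracts the baseline and averages trials", {
  lay <- mini_layout()
  fs <- 512
  n <- 307
  t <- -0.1 + (seq_len(n) - 1) / fs
  one <- array(rnorm(nrow(lay) * n), c(1, nrow(lay), n))
  ep1 <- make_epochs(one, fs, -0.1, lay, "deviant")
  ev1 <- condition_average(ep1, "deviant")
  bl <- t < 0
  expect_equal(ev1$data[4, ], one[1, 4, ] - mean(one[1, 4, bl]))
  expect_lt(abs(mean(ev1$data[4, bl])), 1e-12)
  # opposite-sign trials cancel
  two <- array(0, c(2, nrow(lay), n))
  two[1, , ] <- 1e-6 * sin(2 * pi * 7 * t)[col(matrix(0, nrow(lay), n))]
  two[2, , ] <- -two[1, , ]
  ep2 <- make_epochs(two, fs, -0.1, lay, rep("deviant", 2))
  expect_equal(max(abs(condition_average(ep2, "deviant")$data)), 0,
               tolerance = 1e-18)
  expect_error(condition_average(ep1, "standard"), "no kept trials")
})

test_that("mmn metrics recover a constructed negative peak and handle ties", {
  lay <- mini_layout()
  fs <- 512
  n <- 307
  t <- -0.1 + (seq_len(n) - 1) / fs
  mk_evoked <- function(wave) {
    dat <- matrix(0, nrow(lay), n)
    dat[1, ] <- wave
    structure(list(data = dat, fs = fs, tmin = -0.1, n_trials = 10,
                   condition = "x", baseline = c(-0.1, 0),
                   channel_labels = lay$label, layout = lay, system = "wet"),
              class = "eeg_evoked")
  }
  zero <- mk_evoked(rep(0, n))
  gauss <- mk_evoked(-3e-6 * exp(-(t - 0.125)^2 / (2 * 0.02^2)))
  m <- mmn_metrics(gauss, zero, channel = "S1")
  expect_equal(m$peak_amplitude, -3e-6, tolerance = 1e-3)
  expect_lt(abs(m$peak_latency - 0.125), 1.5 / fs)
  expect_true(m$peak_latency >= 0.1 && m$peak_latency <= 0.15)
  same <- mmn_metrics(zero, zero, channel = "S1")
  expect_equal(same$mean_amplitude, 0)
  expect_equal(same$peak_amplitude, 0)
  const <- mk_evoked(rep(-2e-6, n))
  mc <- mmn_metrics(const, zero, channel = "S1")
  expect_equal(mc$mean_amplitude, -2e-6)
  # tie on a constant window resolves to the earliest sample
  expect_equal(mc$peak_latency, t[which(t >= 0.1)[1]])
  expect_error(mmn_metrics(gauss, zero, channel = "nope"), "channel")
})

test_that("mean amplitude is linear in the data scale", {
  lay <- mini_layout()
  fs <- 512; n <- 307
  set.seed(5)
  dat <- array(rnorm(8 * nrow(lay) * n, sd = 1e-6), c(8, nrow(lay), n))
  ep <- make_epochs(dat, fs, -0.1, lay, rep(c("standard", "deviant"), each = 4))
  m1 <- mmn_metrics(condition_average(ep, "deviant"),
                    condition_average(ep, "standard"), channel = "S1")
  ep3 <- ep; ep3$data <- ep$data * 3
  m3 <- mmn_metrics(condition_average(ep3, "deviant"),
                    condition_average(ep3, "standard"), channel = "S1")
  expect_equal(m3$mean_amplitude, 3 * m1$mean_amplitude, tolerance = 1e-12)
})

test_that("plus-minus SNR: identical trials give the infinity sentinel", {
  lay <- mini_layout()
  fs <- 512; n <- 307
  t <- -0.1 + (seq_len(n) - 1) / fs
  dat <- array(0, c(4, nrow(lay), n))
  for (tr in 1:4) dat[tr, 1, ] <- 1e-6 * exp(-(t - 0.12)^2 / 0.001)
  ep <- make_epochs(dat, fs, -0.1, lay, rep("deviant", 4))
  expect_warning(s <- plus_minus_snr(ep, channel = "S1"), "zero noise")
  expect_identical(s, Inf)
  expect_error(plus_minus_snr(make_epochs(dat[1, , , drop = FALSE], fs, -0.1,
                                          lay, "deviant"), channel = "S1"),
               "at least 2")
})

test_that("plus-minus SNR is near 1 for pure noise and grows with trial count", {
  lay <- mini_layout()
  fs <- 512; n <- 128
  snr_of <- function(n_trials, template_gain) {
    t <- (seq_len(n) - 1) / fs
    tmpl <- template_gain * exp(-(t - 0.125)^2 / (2 * 0.02^2))
    dat <- array(rnorm(n_trials * nrow(lay) * n, sd = 1), c(n_trials, nrow(lay), n))
    for (tr in seq_len(n_trials)) dat[tr, 1, ] <- dat[tr, 1, ] + tmpl
    plus_minus_snr(make_epochs(dat, fs, 0, lay, rep("deviant", n_trials)),
                   channel = "S1")
  }
  set.seed(11)
  null_mean <- mean(replicate(60, snr_of(16, 0)))
  expect_equal(null_mean, 1, tolerance = 0.1)
  set.seed(12)
  with_sig <- vapply(c(8, 32, 128), function(k) {
    mean(replicate(10, snr_of(k, 2)))
  }, numeric(1))
  expect_true(all(diff(with_sig) > 0))
})
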