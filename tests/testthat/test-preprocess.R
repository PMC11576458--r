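test_that("mastoid re-referencing subtracts the mastoid mean and is idempotent", {
  lay <- mini_layout()
  set.seed(1)
  dat <- matrix(rnorm(nrow(lay) * 256), nrow(lay))
  rec <- mini_recording(dat)
  out <- rereference_mastoids(rec)
  ref <- colMeans(dat[match(c("M1", "M2"), lay$label), ])
  expect_equal(out$data["S3", ], dat[3, ] - ref)
  twice <- rereference_mastoids(out)
  expect_equal(twice$data, out$data, tolerance = 1e-12)
})

test_that("zero mastoids leave data unchanged; mastoid-equal data zeroes out", {
  lay <- mini_layout()
  dat <- matrix(rnorm(nrow(lay) * 128), nrow(lay))
  dat[match(c("M1", "M2"), lay$label), ] <- 0
  rec <- mini_recording(dat)
  expect_equal(rereference_mastoids(rec)$data["S1", ], dat[1, ])
  common <- matrix(rep(rnorm(128), nrow(lay)), nrow(lay), byrow = TRUE)
  rec2 <- mini_recording(common)
  expect_equal(max(abs(rereference_mastoids(rec2)$data)), 0, tolerance = 1e-12)
  lay_nom <- mini_layout()[1:16, ]
  attr(lay_nom, "system") <- "wet"
  rec3 <- eeg_recording(dat[1:16, ], 512, lay_nom)
  expect_error(rereference_mastoids(rec3), "mastoid")
  expect_warning(rereference_mastoids(rec3, on_missing = "skip"), "mastoid")
})

test_that("band-pass keeps in-band sinusoids, rejects out-of-band and DC", {
  # 120 s so the 0.1 Hz transition band is realizable (33 s kernel)
  fs <- 512
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  lay <- mini_layout()
  dat <- matrix(0, nrow(lay), length(t))
  dat[1, ] <- sin(2 * pi * 50 * t)
  dat[2, ] <- sin(2 * pi * 10 * t)
  dat[3, ] <- 1  # pure DC
  rec <- mini_recording(dat, fs = fs)
  out <- eeg_bandpass(rec, 0.1, 25)
  trim <- seq(20 * fs, length(t) - 20 * fs)  # drop filter edges
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(rms(out$data[1, trim]), 0.1 * rms(dat[1, trim]))
  expect_equal(rms(out$data[2, trim]), rms(dat[2, trim]), tolerance = 0.05)
  expect_lt(abs(mean(out$data[3, trim])), 0.05)
  expect_error(eeg_bandpass(rec, 25, 0.1), "band edges")
  expect_error(eeg_bandpass(rec, 0, 25), "band edges")
})

test_that("bipolar EOG derivation is sample-exact and validates channels", {
  lay <- mini_layout()
  dat <- matrix(rnorm(nrow(lay) * 200), nrow(lay))
  rec <- mini_recording(dat)
  out <- derive_bipolar_eog(rec)
  expect_true(all(c("vEOG", "hEOG") %in% out$channel_labels))
  expect_false(any(c("EOGa", "EOGb", "EOGl") %in% out$channel_labels))
  expect_equal(out$data["vEOG", ],
               dat[match("EOGa", lay$label), ] - dat[match("EOGb", lay$label), ])
  expect_equal(out$data["hEOG", ],
               dat[match("EOGl", lay$label), ] - dat[match("S4", lay$label), ])
  # equal above/below-eye signals null the vertical EOG
  dat2 <- dat; dat2[match("EOGb", lay$label), ] <- dat2[match("EOGa", lay$label), ]
  expect_equal(max(abs(derive_bipolar_eog(mini_recording(dat2))$data["vEOG", ])), 0)
  lay3 <- lay[lay$label != "EOGl", ]
  for (a in c("system", "mmn_channel", "frontocentral", "eog_map", "mastoids"))
    attr(lay3, a) <- attr(lay, a)
  expect_error(derive_bipolar_eog(eeg_recording(dat[lay$label != "EOGl", ], 512, lay3)),
               "missing")
})

test_that("flat and outlier channels are flagged, clean data mostly is not", {
  lay <- mini_layout()
  set.seed(3)
  dat <- matrix(rnorm(nrow(lay) * 2048, sd = 1e-5), nrow(lay))
  dat[5, ] <- 0                      # dead channel
  dat[7, ] <- dat[7, ] * 40          # gross artifact channel
  bads <- detect_bad_channels(mini_recording(dat))
  expect_true(all(c("S5", "S7") %in% bads))
  n_flagged <- vapply(1:20, function(s) {
    set.seed(s)
    length(detect_bad_channels(mini_recording(
      matrix(rnorm(nrow(lay) * 1024, sd = 1e-5), nrow(lay)))))
  }, numeric(1))
  expect_true(all(n_flagged <= 1))
})

test_that("epoching follows the half-open convention and drops out-of-bounds events", {
  lay <- mini_layout()
  rec <- mini_recording(matrix(0, nrow(lay), 8 * 1024), fs = 1024)
  ev <- data.frame(onset_s = c(0.5, 4, 7.9), onset_sample = c(512, 4096, 8090),
                   tone = "standard", is_habituation = FALSE, follows_deviant = FALSE)
  expect_warning(ep <- epoch_recording(rec, ev, -0.1, 0.5), "dropped")
  expect_equal(dim(ep$data), c(2, nrow(lay), 614))  # 0.6 s at 1024 Hz, half-open
  expect_equal(ep$tmin, -0.1)
})

test_that("rest epoching yields floor(duration/8) epochs of 8 s", {
  lay <- mini_layout()
  rec <- mini_recording(matrix(rnorm(nrow(lay) * 300 * 512), nrow(lay)), fs = 512)
  ep <- epoch_recording(rec, NULL, rest_len = 8)
  expect_equal(dim(ep$data)[1], 37)
  expect_equal(dim(ep$data)[3], 4096)
})

test_that("resampling halves the sample count and preserves in-band RMS", {
  lay <- mini_layout()
  fs <- 1024
  t <- seq(-0.1, 0.5 - 1 / fs, by = 1 / fs)
  dat <- array(rep(sin(2 * pi * 10 * t), each = 2 * nrow(lay)),
               c(2, nrow(lay), length(t)))
  ep <- make_epochs(dat, fs, -0.1, lay, rep("standard", 2))
  out <- resample_epochs(ep, 512)
  expect_equal(dim(out$data)[3], 307)
  expect_equal(out$fs, 512)
  mid <- 50:250
  expect_equal(sqrt(mean(out$data[1, 1, mid]^2)), sqrt(mean(sin(2 * pi * 10 * t)^2)),
               tolerance = 0.02)
  expect_identical(resample_epochs(ep, 1024), ep)
  expect_error(resample_epochs(ep, 2048), "upsampling")
})

test_that("peak-to-peak rejection removes exactly the contaminated trials", {
  lay <- mini_layout()
  set.seed(21)
  dat <- array(rnorm(4 * nrow(lay) * 100, sd = 1e-6), c(4, nrow(lay), 100))
  dat[3, 2, 50:100] <- dat[3, 2, 50:100] + 200e-6  # 200 uV step in trial 3
  ep <- make_epochs(dat, 512, 0, lay, rep("standard", 4))
  res <- reject_epochs_ptp(ep, threshold = 150e-6)
  expect_equal(res$n_rejected, 1)
  expect_equal(which(!res$epochs$kept), 3)
  # published 150 mV literal threshold would keep everything
  expect_equal(reject_epochs_ptp(ep, threshold = 0.15)$n_rejected, 0)
  expect_equal(sum(!reject_epochs_ptp(ep, threshold = 0)$epochs$kept), 4)
})

test_that("spherical-spline interpolation reproduces constants and smooth fields", {
  lay <- channel_layout("wet64")
  n_ch <- nrow(lay)
  const <- array(2.5e-6, c(1, n_ch, 10))
  ep <- make_epochs(const, 512, 0, lay, "rest")
  out <- interpolate_bad_channels(ep, c("Cz", "P3"))
  expect_equal(out$data[1, match("Cz", lay$label), ], rep(2.5e-6, 10),
               tolerance = 1e-6)
  # no bads: identity
  ep2 <- make_epochs(array(rnorm(n_ch * 10), c(1, n_ch, 10)), 512, 0, lay, "rest")
  expect_equal(interpolate_bad_channels(ep2, character(0))$data, ep2$data)
  # leave-one-out on a smooth dipolar field over the scalp sensors
  scalp <- lay[lay$type == "scalp", ]
  dip <- c(0.4, 0.3, 0.9); dip <- dip / sqrt(sum(dip^2))
  field <- as.matrix(scalp[, c("x", "y", "z")]) %*% dip
  dat <- array(0, c(1, n_ch, 4))
  dat[1, match(scalp$label, lay$label), ] <- field
  epf <- make_epochs(dat, 512, 0, lay, "rest")
  errs <- vapply(c("Cz", "FCz", "P1", "C3"), function(ch) {
    est <- interpolate_bad_channels(epf, ch)$data[1, match(ch, lay$label), 1]
    abs(est - field[match(ch, scalp$label)]) / max(abs(field))
  }, numeric(1))
  expect_true(all(errs < 0.15))
})

test_that("the inclusion rule requires both trial retention and SNR", {
  rep0 <- list(fraction_trials_retained = 0.9, reasons = character(0))
  expect_true(apply_inclusion_rule(rep0, snr = 1.5)$included)
  expect_false(apply_inclusion_rule(rep0, snr = 0.9)$included)
  rep1 <- list(fraction_trials_retained = 0.6, reasons = character(0))
  r <- apply_inclusion_rule(rep1, snr = 2)
  expect_false(r$included)
  expect_match(r$reasons, "trials")
  expect_false(apply_inclusion_rule(rep0, snr = 1)$included)  # strict inequality
})

test_that("the full preprocessing chain is ordered and logged", {
  sq <- oddball_sequence(n_standards = 10, n_deviants_per_type = 2, seed = 4,
                         n_habituation = 2)
  truth <- ground_truth(seed = 2)
  rec <- simulate_task_recording(sq, truth, mini_layout(), "wet", seed = 5)
  pp <- preprocess_recording(rec, "task",
                             params = modifyList(preproc_defaults(),
                                                 list(ica_components = 8)),
                             seed = 6)
  steps <- sub(":.*", "", pp$epochs$provenance)
  expect_equal(steps, c("rereference", "bandpass", "epoch", "resample",
                        "eog", "ica", "interpolate", "ptp_reject"))
  expect_equal(pp$epochs$fs, 512)
  expect_true(pp$report$fraction_trials_retained >= 0 &&
                pp$report$fraction_trials_retained <= 1)
})
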