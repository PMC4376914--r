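test_that("band-pass preserves in-band sinusoids and removes DC and 50 Hz", {
  fs <- 200
  x10 <- sinusoid(10, 10, fs, amp = 5)
  y10 <- bandpass_filter(x10, fs)
  core <- 401:1600  # avoid edge transients
  expect_equal(max(abs(y10[core])), 5, tolerance = 0.01)

  x50 <- sinusoid(50, 10, fs, amp = 5)
  y50 <- bandpass_filter(x50, fs)
  expect_lt(max(abs(y50[core])), 0.5)  # >= 90% attenuation

  # DC decays on the high-pass filter's ~1/low time scale; probe the
  # interior of a long record
  dc <- rep(3, 120 * fs)
  ydc <- bandpass_filter(dc, fs)
  expect_lt(max(abs(ydc[8001:16000])), 0.05)
})

test_that("50 Hz attenuation matches the filter's analytic transfer function", {
  fs <- 200
  # analytic (digital) magnitude response of the realized design: order-2
  # high-pass then order-4 low-pass, each applied forward-backward, so the
  # end-to-end gain is the product of squared magnitudes
  hp <- signal::butter(2, 0.1 / (fs / 2), type = "high")
  lp <- signal::butter(4, 35 / (fs / 2), type = "low")
  h <- function(flt, f) {
    w <- 2 * pi * f / fs
    z <- exp(1i * w)
    abs(sum(flt$b * z^-(seq_along(flt$b) - 1)) /
          sum(flt$a * z^-(seq_along(flt$a) - 1)))
  }
  gain <- (h(hp, 50) * h(lp, 50))^2
  y <- bandpass_filter(sinusoid(50, 20, fs, amp = 1), fs)
  measured <- max(abs(y[2001:2800]))
  expect_equal(measured, gain, tolerance = 0.05)
  expect_lt(gain, 0.1)  # >= 90% attenuation by design
})

test_that("band-pass rejects cutoffs at or beyond Nyquist", {
  expect_error(bandpass_filter(rnorm(100), 60, high = 35), "Nyquist")
  expect_error(bandpass_filter(rnorm(100), 200, low = 40, high = 35),
               "0 < low < high")
})

test_that("epoching yields fixed 2-s windows and discards partial tails", {
  fs <- 200
  es <- epoch_and_reject(rnorm(30 * fs, 0, 5), fs)
  expect_equal(nrow(es$epochs), 15)
  expect_equal(ncol(es$epochs), 400)
  es2 <- epoch_and_reject(rnorm(30 * fs + 399, 0, 5), fs)
  expect_equal(nrow(es2$epochs), 15)  # trailing partial window dropped
  expect_error(epoch_and_reject(rnorm(399), fs), "segment error")
})

test_that("artifact rejection triggers strictly above the 70 uV threshold", {
  fs <- 200
  x <- rep(0, 10 * fs)
  x[500] <- 100   # spike inside epoch 2
  es <- epoch_and_reject(x, fs)
  expect_false(es$kept[2])
  expect_true(all(es$kept[-2]))
  x[500] <- 69
  expect_true(all(epoch_and_reject(x, fs)$kept))
  x[500] <- -100  # negative excursions count too
  expect_false(epoch_and_reject(x, fs)$kept[2])
  # peak-to-peak criterion flags large swings that absolute |x| misses
  y <- rep(c(-40, 40), 200 * 5)
  expect_true(all(epoch_and_reject(y, fs)$kept))
  expect_false(any(epoch_and_reject(y, fs, criterion = "peak_to_peak")$kept))
})

test_that("injected artifact rate is recovered within binomial error", {
  s3 <- gen_study3(n_subjects = 2, visualization_sec = 20, listening_sec = 20,
                   artifact_rate = 0.05, seed = 77)
  fracs <- purrr::map_dbl(s3$recordings, function(r) {
    attr(eeg_iai_table(r, filter = TRUE), "rejection_fraction")
  })
  rej <- mean(fracs)  # equal epoch counts per subject
  # artifacts hit 2-s grid epochs jointly across channels: 280 grid epochs
  # per subject, 2 subjects => binomial(560, 0.05); 4-sigma envelope
  expect_lt(abs(rej - 0.05), 4 * sqrt(0.05 * 0.95 / 560))
})

test_that("alpha power matches the Parseval closed form for in-band sinusoids", {
  fs <- 200
  for (A in c(1, 4)) {
    es <- epoch_and_reject(sinusoid(10, 30, fs, amp = A), fs, threshold = Inf)
    # one-sided PSD of a pure bin-centred sinusoid: A^2 * N / (2 fs) at its
    # bin, averaged over the 11 bins spanning 8-13 Hz at 0.5 Hz resolution
    closed_form <- (A^2 * 400 / (2 * fs)) / 11
    expect_equal(alpha_power(es), closed_form, tolerance = 0.01 * closed_form)
  }
  # quadrupling amplitude multiplies power by 16
  e1 <- epoch_and_reject(sinusoid(10, 30, fs, amp = 1), fs)
  e4 <- epoch_and_reject(sinusoid(10, 30, fs, amp = 4), fs)
  expect_equal(alpha_power(e4) / alpha_power(e1), 16, tolerance = 1e-6)
})

test_that("out-of-band energy does not leak into alpha power", {
  fs <- 200
  e20 <- epoch_and_reject(sinusoid(20, 30, fs, amp = 5), fs)
  e10 <- epoch_and_reject(sinusoid(10, 30, fs, amp = 5), fs)
  expect_lt(alpha_power(e20), 1e-6 * alpha_power(e10))
  # spectral additivity: 10 Hz + 20 Hz has the alpha power of 10 Hz alone
  mix <- sinusoid(10, 30, fs, amp = 3) + sinusoid(20, 30, fs, amp = 5)
  emix <- epoch_and_reject(mix, fs, threshold = Inf)
  expect_equal(alpha_power(emix), alpha_power(epoch_and_reject(
    sinusoid(10, 30, fs, amp = 3), fs)), tolerance = 0.01)
})

test_that("all-rejected epoch sets raise a rejection error with counts", {
  fs <- 200
  es <- epoch_and_reject(rep(500, 10 * fs), fs)
  expect_false(any(es$kept))
  expect_error(alpha_power(es), "rejection error")
})

test_that("IAI identities: equal powers give 1, ratios follow amplitude squared", {
  expect_equal(compute_iai(c(2, 2), 2), 1.0)
  expect_equal(compute_iai(c(4, 4), 2), 2.0)
  expect_error(compute_iai(c(0, 1), 2), "degenerate-power")
  expect_error(compute_iai(c(1, 1), numeric(0)), "degenerate-power")
  # amplitude halved in task => power ratio 4
  fs <- 200
  pb <- alpha_power(epoch_and_reject(sinusoid(10, 30, fs, amp = 4), fs))
  pt <- alpha_power(epoch_and_reject(sinusoid(10, 30, fs, amp = 2), fs))
  expect_equal(compute_iai(c(pb, pb), pt), 4.0, tolerance = 1e-9)
})

test_that("IAI is invariant to rescaling the whole recording", {
  s3 <- gen_study3(n_subjects = 1, visualization_sec = 8, listening_sec = 8,
                   artifact_rate = 0, seed = 5)
  rec <- s3$recordings[[1]]
  rec2 <- rec
  rec2$signal <- rec2$signal * 3
  i1 <- eeg_iai_table(rec, filter = FALSE, threshold = Inf)
  i2 <- eeg_iai_table(rec2, filter = FALSE, threshold = Inf)
  expect_equal(i1$iai, i2$iai, tolerance = 1e-12)
})

test_that("aggregate_iai averages the imagery electrodes, visualization only", {
  tab <- tidyr::expand_grid(
    subject_id = "s1",
    electrode = c("O1", "O2", "P3", "P4", "Fp1"),
    domain = "ethical",
    phase = c("listening", "visualization"))
  tab$iai <- ifelse(tab$phase == "visualization",
                    c(1.00, 1.02, 1.04, 1.06, 9)[match(tab$electrode,
                      c("O1", "O2", "P3", "P4", "Fp1"))], 5)
  agg <- aggregate_iai(tab)
  expect_equal(agg$iai, 1.03)  # frontal and listening rows excluded
  expect_error(aggregate_iai(tab[tab$electrode != "P3", ]), "coverage error")
})
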