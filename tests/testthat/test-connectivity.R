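test_that("segment_epochs applies the amplitude rule and keeps the earliest", {
  fs <- 500
  clean <- matrix(sin(2 * pi * 10 * seq_len(160 * fs) / fs) * 50,
                  nrow = 3, ncol = 160 * fs, byrow = TRUE)
  ts <- regional_ts(clean, fs)
  ep <- segment_epochs(ts)
  expect_length(ep, 4L)
  expect_true(all(vapply(ep, function(e) ncol(e$data) == 20000L, logical(1))))

  # a 150 uV spike in epoch 2 of 5 removes exactly that epoch
  spiky <- matrix(0, nrow = 2, ncol = 5 * 40 * 100)
  spiky[1, ] <- 10 * sin(2 * pi * 10 * seq_len(ncol(spiky)) / 100)
  spiky[2, 40 * 100 + 500] <- 150
  ep2 <- segment_epochs(regional_ts(spiky, 100), n_keep = NULL)
  expect_length(ep2, 4L)
  starts <- c(0, 2, 3, 4) * 4000 + 1   # epoch 2 absent
  got <- vapply(ep2, function(e) e$data[1, 1], numeric(1))
  expect_equal(got, spiky[1, starts])

  expect_error(segment_epochs(regional_ts(matrix(0, 1, 30 * 100), 100)),
               "shorter")
  short <- regional_ts(matrix(200, 1, 80 * 100), 100)   # all epochs rejected
  expect_error(segment_epochs(short), "0 artifact-free")
})

test_that("band-pass passes in-band tones and rejects out-of-band energy", {
  fs <- 200
  t <- seq_len(20 * fs) / fs
  ts <- regional_ts(rbind(sin(2 * pi * 10 * t),
                          sin(2 * pi * 20 * t),
                          rep(1, length(t))), fs)
  f <- bandpass(ts, "alpha")
  mid <- 1000:3000
  expect_equal(max(abs(f$data[1, mid])), 1, tolerance = 0.05)
  expect_lt(sqrt(mean(f$data[2, ]^2)), 0.1)       # 20 Hz tone suppressed
  expect_lt(max(abs(f$data[3, ])), 1e-6)          # DC is outside all bands
  expect_error(bandpass(ts, c(10, 150)), "Nyquist")
  expect_error(bandpass(ts, "nope"), "unknown band")
})

test_that("instantaneous phase behaves like the analytic phase of a tone", {
  fs <- 250
  t <- seq_len(10 * fs) / fs
  ts <- regional_ts(rbind(sin(2 * pi * 10 * t),
                          cos(2 * pi * 10 * t),
                          3.7 * sin(2 * pi * 10 * t)), fs)
  ph <- instantaneous_phase(ts, margin = 1)
  expect_equal(attr(ph, "margin_samples"), 250L)
  mid <- 500:2000
  # unwrapped slope ~ 2*pi*10 rad/s
  slope <- mean(diff(ph[1, mid]) %% (2 * pi)) * fs
  expect_equal(slope, 2 * pi * 10, tolerance = 0.01)
  # cos leads sin by pi/2
  d <- (ph[2, mid] - ph[1, mid]) %% (2 * pi)
  expect_equal(mean(d), pi / 2, tolerance = 0.01)
  # amplitude invariance
  expect_equal(ph[3, ], ph[1, ], tolerance = 1e-8)
  expect_error(instantaneous_phase(regional_ts(matrix(0, 2, 100), 100)),
               "zero")
})

test_that("plv matches its definition and limits", {
  n <- 20000
  withr::with_seed(42, {
    px <- runif(n, -pi, pi)
    py <- runif(n, -pi, pi)
  })
  expect_equal(plv(px, px), 1)
  expect_equal(plv(px, px + pi / 2), 1)
  expect_lt(plv(px, py), 0.02)   # E[PLV] ~ sqrt(pi)/2/sqrt(n) ~ 0.006
  # definition oracle on a tiny case
  a <- c(0, 1, 2)
  b <- c(0.5, 0.2, 3)
  expect_equal(plv(a, b), abs(mean(exp(1i * (a - b)))))
  expect_error(plv(1:3, 1:4), "mismatch")
})

test_that("connectome averages epochs and keeps the matrix contract", {
  fs <- 128
  pm <- planted_model(n_regions = 8, n_pos = 1, n_neg = 0, seed = 3)
  ts <- gen_coupled_timeseries(0, pm, fs = fs, n_epochs = 2, epoch_len = 15,
                               mixing = 1, seed = 8)
  eps <- segment_epochs(ts, epoch_len = 15, n_keep = 2)
  cn <- connectome(eps, "alpha")
  expect_equal(unclass(cn), t(unclass(cn)))
  expect_true(all(cn >= 0 & cn <= 1))
  expect_equal(diag(cn), rep(0, 8))
  pair <- edge_index(8)[pm$pos_edges[1L], ]
  expect_gt(cn[pair[1L], pair[2L]], 0.95)   # perfectly coupled pair
  # averaging across epochs equals the mean of single-epoch connectomes
  c1 <- connectome(eps[1], "alpha")
  c2 <- connectome(eps[2], "alpha")
  expect_equal(unclass(cn), (unclass(c1) + unclass(c2)) / 2)
  expect_error(connectome(list(), "alpha"), "non-empty")
})
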