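# Equiripple design, zero-phase filtering, Hilbert decomposition, channel
# selection.

test_that("gamma band design meets its frequency-response contract", {
  h <- design_bandpass(default_bands()$gamma, fs = 256)
  expect_length(h, 257)
  expect_gte(fir_response(h, 35, 256), 0.89)
  expect_lte(fir_response(h, 20, 256), 0.01)
  expect_equal(h, rev(h))                     # linear phase
})

test_that("default designs meet ripple and attenuation targets", {
  # single-pass: <= 1 dB passband ripple and >= 40 dB stopband attenuation
  # for the four bands with full-width transitions; the 1-12 Hz band's
  # sub-hertz lower edge is certified on the effective zero-phase (squared)
  # response the pipeline applies
  bands <- default_bands()
  edges <- list(`delta-theta-alpha` = c(0.2, 14), alpha = c(2, 16),
                beta = c(9, 34), gamma = c(26, 44),
                `upper-gamma` = c(36, 54))
  for (nm in names(bands)) {
    b <- bands[[nm]]
    h <- design_bandpass(b, 256)
    expect_equal(h, rev(h), tolerance = 1e-12)
    pass <- fir_response(h, seq(b$low_hz + 0.5, b$high_hz - 0.5, 0.1), 256)
    stop_f <- c(seq(0, edges[[nm]][1], length.out = 20),
                seq(edges[[nm]][2], 127.9, length.out = 50))
    stopm <- fir_response(h, stop_f, 256)
    if (nm == "delta-theta-alpha") {
      expect_lt(20 * log10(max(pass) / min(pass)), 2 * 1)
      expect_lt(max(stopm^2), 10^(-40 / 20))
    } else {
      expect_lt(20 * log10(max(pass) / min(pass)), 1)
      expect_lt(max(stopm), 10^(-40 / 20))
    }
  }
})

test_that("infeasible bands and even tap counts are rejected", {
  expect_error(design_bandpass(band_spec("bad", 100, 130), 256), "Nyquist")
  expect_error(design_bandpass(default_bands()$gamma, 256, numtaps = 256),
               "odd")
})

test_that("an in-band sinusoid passes with unit gain and zero lag", {
  fs <- 256
  n <- 20 * fs
  x <- sin(2 * pi * 9 * (0:(n - 1)) / fs)
  rec <- eeg_record(matrix(x, 1), fs)
  y <- bandpass_filter(rec, default_bands()$alpha)$data[1, ]
  v <- 1000:(n - 1000)
  expect_equal(sqrt(mean(y[v]^2)) / sqrt(mean(x[v]^2)), 1, tolerance = 0.05)
  # zero-phase: cross-correlation peaks at lag 0
  cc <- stats::ccf(y[v], x[v], lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("zero-phase filtering matches forward-backward FIR in the interior", {
  set.seed(5)
  h <- design_bandpass(default_bands()$beta, 256)
  x <- rnorm(4000)
  mine <- plavdet:::zero_phase_fir(x, h)
  ref <- signal::filtfilt(signal::Ma(h), x)
  inner <- 600:3400
  expect_lt(max(abs(mine[inner] - ref[inner])), 1e-10)
})

test_that("DC offsets are rejected by the beta band and zeros map to zeros", {
  fs <- 256
  rec <- eeg_record(matrix(50, 1, 10 * fs), fs)   # pure DC at 50 uV
  y <- bandpass_filter(rec, default_bands()$beta)$data[1, ]
  expect_lt(abs(mean(y[1000:1500])), 1e-6 * 50)
  recz <- eeg_record(matrix(0, 1, 10 * fs), fs)
  expect_true(all(bandpass_filter(recz, default_bands()$beta)$data == 0))
})

test_that("records shorter than 3 filter lengths are rejected", {
  rec <- eeg_record(matrix(rnorm(500), 1), 256)
  expect_error(bandpass_filter(rec, default_bands()$gamma), "3 filter length")
})

test_that("Hilbert decomposition recovers amplitude and frequency of a tone", {
  fs <- 256
  n <- 10 * fs
  x <- cos(2 * pi * 10 * (0:(n - 1)) / fs)
  a <- hilbert_decompose(x)
  v <- a$valid[1]:a$valid[2]
  expect_lt(max(abs(a$aa[v] - 1)), 0.02)
  expect_true(all(a$ap >= -pi & a$ap <= pi))
  # unwrapped phase increments give the instantaneous frequency
  inc <- diff(a$ap[v])
  inc <- (inc + pi) %% (2 * pi) - pi
  expect_equal(mean(inc), 2 * pi * 10 / fs, tolerance = 0.01)
})

test_that("Hilbert decomposition tracks the envelope of an AM swept tone", {
  fs <- 256
  n <- 30 * fs
  t <- (0:(n - 1)) / fs
  f_inst <- 8 + 3 * t / max(t)                 # 8 -> 11 Hz sweep
  phi <- 2 * pi * cumsum(f_inst) / fs
  env <- 1 + 0.3 * sin(2 * pi * 0.1 * t)
  rec <- eeg_record(matrix(env * cos(phi), 1), fs)
  y <- bandpass_filter(rec, default_bands()$alpha)$data[1, ]
  a <- hilbert_decompose(y)
  v <- a$valid[1]:a$valid[2]
  expect_lt(max(abs(a$aa[v] / env[v] - 1)), 0.05)
})

test_that("degenerate Hilbert inputs raise errors", {
  expect_error(hilbert_decompose(numeric(600)), "all-zero")
  expect_error(hilbert_decompose(rnorm(32)), "64 samples")
})

test_that("channel selection follows the SD rule with documented ties", {
  set.seed(9)
  n <- 2000
  data <- rbind(rnorm(n, sd = 1), rnorm(n, sd = 5), rnorm(n, sd = 2))
  rec <- eeg_record(data, 256, c("A", "B", "C"))
  sel <- select_channels(rec, auto_artifact = FALSE)
  expect_equal(sel$working, "B")
  expect_equal(sel$reference, "A")

  # invariant to channel order
  rec2 <- subset_channels(rec, c("C", "A", "B"))
  sel2 <- select_channels(rec2, auto_artifact = FALSE)
  expect_equal(sel2[c("working", "reference")],
               sel[c("working", "reference")])

  # exact tie in max SD -> lowest channel index wins
  tie <- eeg_record(rbind(c(1, -1, 1, -1), c(1, -1, 1, -1), c(0.1, -0.1, 0.1, -0.1)),
                    256, c("X", "Y", "Z"))
  selt <- select_channels(tie, auto_artifact = FALSE)
  expect_equal(selt$working, "X")
  expect_equal(selt$reference, "Z")

  expect_error(select_channels(rec, blocklist = c("A", "B"),
                               auto_artifact = FALSE),
               "fewer than 2")
  expect_error(select_channels(rec, blocklist = c("A", "B", "C"),
                               auto_artifact = FALSE),
               "fewer than 2")
})

test_that("artifact channels are flagged by the amplitude rule", {
  set.seed(11)
  n <- 10000
  clean <- rnorm(n, sd = 50)
  dirty <- clean
  dirty[sample(n, 0.02 * n)] <- 800           # 2 percent of samples at 800 uV
  rec <- eeg_record(rbind(clean, dirty, clean), 256, c("OK1", "BAD", "OK2"))
  expect_equal(flag_artifact_channels(rec), "BAD")
  sel <- select_channels(rec)                 # auto artifact removal on
  expect_false("BAD" %in% unlist(sel))
})
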