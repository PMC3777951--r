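test_that("onset lands at the start of a ramp after a flat baseline", {
  fs <- 1000
  j <- 300
  x <- c(rep(0, j), seq(0, 60, length.out = 200), rep(60, 100))
  onset <- detect_onset(x, fs, frame_ms = 10)
  expect_gte(onset, j)
  expect_lte(onset, j + 10)   # within [j, j + frame]
  expect_lt(onset, which.max(x))

  expect_error(detect_onset(rep(1, 500), fs), class = "cardiofp_detection_failure")
})

test_that("onset on a noisy synthetic complex is within 2 ms of truth", {
  fs <- 10000
  cfg <- quick_cfg(sample_rate = fs)
  cplx <- synth_complex(cfg)
  pad <- round(0.1 * fs)   # 100 ms baseline before the beat
  x0 <- c(numeric(pad), cplx$samples, numeric(pad))
  set.seed(8)
  for (i in 1:3) {
    x <- x0 + rnorm(length(x0), 0, 0.01 * cfg$spike_amplitude_uv)
    onset <- detect_onset(x, fs)
    expect_lt(abs(onset - (pad + 1)) / fs * 1000, 2)
  }
})

test_that("trapezium-area offset finds the corner of a linear return to baseline", {
  fs <- 1000
  # spike, valley, repolarisation wave with straight descent to baseline at q
  x <- c(numeric(50), 100, -40, numeric(48),
         seq(0, 30, length.out = 60),            # rise to repol peak
         seq(30, 0, length.out = 100),           # straight descent, corner at q
         numeric(150))
  q <- 50 + 2 + 48 + 60 + 100
  off <- detect_offset_tra(x, fs)
  expect_equal(off, q, tolerance = 1)

  # strictly decreasing tail, no flat segment -> offset at the last sample
  y <- c(numeric(20), 100, -40, seq(30, 0.1, length.out = 150))
  expect_equal(detect_offset_tra(y, fs), length(y))

  expect_error(detect_offset_tra(c(numeric(10), 100, -5), fs),
               class = "cardiofp_detection_failure")
})

test_that("offset equals the exhaustive brute-force argmax on varied waveforms", {
  set.seed(12)
  fs <- 2000
  waves <- list(
    synth_complex(quick_cfg(sample_rate = fs))$samples,
    synth_complex(quick_cfg(sample_rate = fs, fpd_ms = 430,
                            beating_rate_bpm = 55))$samples,
    c(numeric(40), 80, -30, numeric(30), dnorm(1:300, 150, 40) * 2000, numeric(60))
  )
  waves <- c(waves, lapply(waves, function(w) {
    c(numeric(25), w, numeric(40)) + rnorm(length(w) + 65, 0, 0.5)
  }))
  for (w in waves) {
    expect_equal(detect_offset_tra(w, fs), brute_tra(w))
    expect_equal(detect_offset_tra(w, fs, search_start = "post-spike-valley"),
                 brute_tra(w, "post-spike-valley"))
  }
})

test_that("time-shifting a waveform shifts both landmarks by the same amount", {
  fs <- 2000
  s <- synth_complex(quick_cfg(sample_rate = fs))$samples
  x1 <- c(numeric(200), s, numeric(300))
  x2 <- c(numeric(350), s, numeric(150))
  expect_equal(detect_onset(x2, fs) - detect_onset(x1, fs), 150)
  expect_equal(detect_offset_tra(x2, fs) - detect_offset_tra(x1, fs), 150)
})

test_that("FPD, Bazett correction and AUC arithmetic are exact", {
  fs <- 1000
  x <- c(numeric(100), rep(1, 301), numeric(100))

  # 300 ms at 60 bpm: RR = 1 s, cFPD = FPD
  m <- measure_fpd(x, onset = 101, offset = 401, beating_rate = 60,
                   sample_rate = fs)
  expect_equal(m$fpd_ms, 300)
  expect_equal(m$cfpd_ms, 300)

  # published-style FPD/rate pair: 410.93 ms at 113 bpm -> ~563.9 ms
  m2 <- measure_fpd(numeric(12000), onset = 100,
                    offset = 100 + round(410.93 / 1000 * fs),
                    beating_rate = 113, sample_rate = fs)
  expect_equal(m2$cfpd_ms, 410.93 / sqrt(60 / 113), tolerance = 1e-3)
  expect_equal(round(m2$cfpd_ms, 1), 563.9, tolerance = 0.2)

  # unit rectangle: 1 uV for exactly 100 ms -> AUC 100 uV*ms
  r <- c(numeric(50), rep(1, 101), numeric(50))
  m3 <- measure_fpd(r, onset = 51, offset = 151, beating_rate = 60,
                    sample_rate = fs)
  expect_equal(m3$auc_uv_ms, 100)

  expect_error(measure_fpd(x, onset = 200, offset = 100, beating_rate = 60,
                           sample_rate = fs),
               class = "cardiofp_ordering")
})

test_that("Bazett correction is the identity at 60 bpm and increasing in rate", {
  x <- c(numeric(100), rep(1, 500), numeric(100))
  cfpd <- sapply(c(40, 60, 90, 120, 150), function(br) {
    measure_fpd(x, 101, 401, beating_rate = br, sample_rate = 1000)$cfpd_ms
  })
  expect_equal(cfpd[2], 300)
  expect_true(all(diff(cfpd) > 0))
})

test_that("manual landmarks use the same arithmetic and are flagged", {
  fs <- 1000
  x <- c(numeric(50), rep(2, 400), numeric(50))
  m <- manual_landmarks(x, onset_ms = 10, offset_ms = 310, beating_rate = 60,
                        sample_rate = fs)
  expect_equal(m$fpd_ms, 300)
  expect_equal(m$onset_mode, "manual")
  expect_equal(m$offset_mode, "manual")

  expect_error(manual_landmarks(x, 310, 310, 60, fs), class = "cardiofp_range")
  expect_error(manual_landmarks(x, -5, 100, 60, fs), class = "cardiofp_range")

  # mixed manual onset + automatic offset is allowed, with per-landmark flags
  s <- synth_complex(quick_cfg(sample_rate = fs))$samples
  w <- new_fp_waveform(c(numeric(100), s, numeric(100)), fs,
                       source = list(beating_rate_bpm = 60))
  mm <- analyze_waveform(w, onset = 100, offset = "auto")
  expect_equal(mm$onset_mode, "manual")
  expect_equal(mm$offset_mode, "auto")
})
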