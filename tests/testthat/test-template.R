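test_that("complex extraction windows follow the smallest beat-beat interval", {
  fs <- 1000
  idx <- seq(1000, 5500, by = 500)  # 10 peaks, interval 500 ms
  trace <- numeric(7000)
  trace[idx] <- 100
  peaks <- structure(tibble::tibble(index = idx), sample_rate = fs,
                     class = c("fp_peaks", class(tibble::tibble())))

  cx <- extract_complexes(trace, peaks, fs, window_ms = "auto")
  expect_equal(attr(cx, "window_samples"), 500)
  expect_lte(10 - nrow(cx), 2)
  # window centred on the peak
  expect_true(all(abs(cx$peak_local - 250) <= 1))
  for (r in seq_len(nrow(cx))) {
    expect_equal(which.max(cx$samples[[r]]), cx$peak_local[r])
  }

  # a beat too close to the trace edge is dropped and counted
  peaks2 <- structure(tibble::tibble(index = c(10, idx)), sample_rate = fs,
                      class = class(peaks))
  cx2 <- extract_complexes(trace, peaks2, fs, window_ms = 500)
  expect_equal(attr(cx2, "n_dropped"), 1)
  expect_false(1 %in% cx2$beat)

  # explicit window length in ms
  cx3 <- extract_complexes(trace, peaks, fs, window_ms = 100)
  expect_true(all(lengths(cx3$samples) == 100))

  expect_error(extract_complexes(trace[1:300], peaks, fs, window_ms = 500),
               class = "cardiofp_parameter")
})

test_that("default template is the complex nearest the recording midpoint", {
  fs <- 1000
  idx <- seq(500, 6500, by = 1000)  # 7 peaks uniformly spread over 7 s
  trace <- numeric(7000)
  trace[idx] <- 50
  peaks <- structure(tibble::tibble(index = idx), sample_rate = fs,
                     class = c("fp_peaks", class(tibble::tibble())))
  cx <- extract_complexes(trace, peaks, fs, window_ms = 400)
  expect_equal(nrow(cx), 7)

  tm <- select_template(cx)
  expect_equal(attr(tm, "template_row"), 4)
  expect_equal(attr(tm, "selection_mode"), "default-centre")

  tm2 <- select_template(cx, mode = 2)
  expect_identical(tm2$samples[[1]], cx$samples[[2]])

  expect_error(select_template(cx[0, ]), class = "cardiofp_insufficient_data")
  expect_error(select_template(cx, mode = 99), class = "cardiofp_lookup")
})

test_that("correlation coefficient is exact on identities and lags", {
  x <- sin(seq(0, 4 * pi, length.out = 200)) * exp(-seq(0, 3, length.out = 200))
  r <- correlation_coefficient(x, x, max_lag = 0)
  expect_equal(r$coefficient, 1)
  expect_equal(r$best_lag, 0)

  expect_equal(correlation_coefficient(x, -x, max_lag = 0)$coefficient, -1)

  # delayed copy: perfect score at |lag| = 3
  y <- c(rep(x[1], 3), x[1:197])
  r <- correlation_coefficient(x, y, max_lag = 5)
  expect_equal(r$coefficient, 1, tolerance = 1e-6)
  expect_equal(abs(r$best_lag), 3)

  expect_error(correlation_coefficient(x, rep(2, 200), max_lag = 0),
               class = "cardiofp_undefined_correlation")
  expect_error(correlation_coefficient(x, x, max_lag = 60),
               class = "cardiofp_parameter")
  expect_error(correlation_coefficient(x, x[1:100]), class = "cardiofp_parameter")
})

test_that("coefficient matches a brute-force lagged Pearson oracle", {
  set.seed(42)
  for (rep in 1:5) {
    a <- cumsum(rnorm(120))
    b <- cumsum(rnorm(120))
    L <- 10
    # independent oracle: plain cor() on every overlap
    cors <- sapply(-L:L, function(n) {
      i <- (1 + max(0, n)):(120 + min(0, n))
      cor(a[i], b[i - n])
    })
    got <- correlation_coefficient(a, b, max_lag = L)
    expect_equal(got$coefficient, max(cors), tolerance = 1e-12)
    expect_equal(cors[got$best_lag + L + 1], got$coefficient, tolerance = 1e-12)
  }
})

test_that("coefficient is symmetric at lag 0 and invariant to gain and offset", {
  set.seed(7)
  a <- rnorm(100)
  b <- rnorm(100)
  c0 <- function(x, y) correlation_coefficient(x, y, max_lag = 0)$coefficient
  expect_equal(c0(a, b), c0(b, a))
  expect_equal(c0(a, 3.7 * b + 12), c0(a, b))
  expect_equal(c0(a / 5 - 2, b), c0(a, b))
  # the raw 1/N product-sum variant is scale-dependent, by design
  raw <- function(x, y) correlation_coefficient(x, y, max_lag = 0,
                                                method = "raw")$coefficient
  expect_equal(raw(a, 2 * b), 2 * raw(a, b))
})

test_that("classification rejects planted premature beats at CF 0.98", {
  fs <- 20000
  cfg <- synth_config(sample_rate = fs, duration_s = 30,
                      beating_rate_bpm = 75, fpd_ms = 350,
                      rate_jitter = 0.01, noise_sd_uv = 10,  # 5% of spike
                      premature_prob = 0.2, seed = 42)
  out <- synth_recording(cfg)
  trace <- lowpass_filter(rec_trace(out$recording), fs)
  peaks <- detect_peaks(trace, fs)
  cx <- extract_complexes(trace, peaks, fs)
  labels <- match_beat_labels(peaks$index[cx$beat], out$truth, fs)
  expect_false(any(is.na(labels)))
  # template: a normal beat near the middle of the recording (choosing a
  # premature template would instead single out the premature beats)
  normal_rows <- which(labels == "normal")
  tmpl_row <- normal_rows[which.min(abs(normal_rows - nrow(cx) / 2))]
  rep_ <- classify_complexes(cx, select_template(cx, mode = tmpl_row), cf = 0.98)
  n_prem <- sum(labels == "premature")
  expect_gte(n_prem, 5)
  expect_true(all(!rep_$accepted[labels == "premature"]))
  expect_gte(mean(rep_$accepted[labels == "normal"]), 0.95)

  # the dominant-morphology mode never picks a premature template here
  dom <- select_template(cx, mode = "dominant")
  expect_equal(labels[attr(dom, "template_row")], "normal")

  expect_error(classify_complexes(cx, select_template(cx), cf = 0),
               class = "cardiofp_parameter")
  # the template itself is accepted with coefficient 1 at any CF <= 1
  rep1 <- classify_complexes(cx, select_template(cx, mode = tmpl_row), cf = 1)
  expect_true(rep_$accepted[tmpl_row])
  expect_equal(rep1$coefficient[tmpl_row], 1)
})

test_that("the accepted set never grows as CF rises", {
  cfg <- synth_config(sample_rate = 4000, duration_s = 25,
                      beating_rate_bpm = 90, rate_jitter = 0.02,
                      noise_sd_uv = 15, premature_prob = 0.2, seed = 5)
  out <- synth_recording(cfg)
  trace <- lowpass_filter(rec_trace(out$recording), 4000)
  peaks <- detect_peaks(trace, 4000)
  cx <- extract_complexes(trace, peaks, 4000)
  tm <- select_template(cx)
  prev <- rep(TRUE, nrow(cx))
  for (cf in c(0.88, 0.93, 0.98, 0.995)) {
    acc <- classify_complexes(cx, tm, cf = cf)$accepted
    expect_true(all(prev | !acc))  # acc subset of prev
    prev <- acc
  }
})

test_that("a degenerate complex is rejected with a flag, not an abort", {
  x <- sin(seq(0, 2 * pi, length.out = 50))
  cx <- as_complexes(list(x, rep(3, 50), -x), sample_rate = 1000)
  rep_ <- classify_complexes(cx, cx[1, ], cf = 0.9, max_lag = 0)
  expect_equal(rep_$degenerate, c(FALSE, TRUE, FALSE))
  expect_equal(rep_$accepted, c(TRUE, FALSE, FALSE))
})

test_that("ensemble averaging reduces noise at the law-of-large-numbers rate", {
  set.seed(99)
  clean <- synth_complex(quick_cfg(sample_rate = 2000))$samples
  sigma <- 5

  noisy <- lapply(1:100, function(i) clean + rnorm(length(clean), 0, sigma))
  cx <- as_complexes(noisy, 2000)
  avg <- ensemble_average(accept_all_report(cx), cx)
  expect_equal(avg$n_ensembles, 100)
  rmse <- sqrt(mean((avg$samples - clean)^2))
  expect_lte(rmse, 1.5 * sigma / sqrt(100))

  # N^(-1/2) scaling within a factor 1.5 across N = 4, 16, 64
  rmse_n <- sapply(c(4, 16, 64), function(N) {
    reps <- lapply(seq_len(N), function(i) clean + rnorm(length(clean), 0, sigma))
    cxn <- as_complexes(reps, 2000)
    a <- ensemble_average(accept_all_report(cxn), cxn)
    sqrt(mean((a$samples - clean)^2))
  })
  expected <- sigma / sqrt(c(4, 16, 64))
  expect_true(all(rmse_n / expected < 1.5 & rmse_n / expected > 1 / 1.5))
})

test_that("ensemble averaging identities hold", {
  s <- synth_complex(quick_cfg(sample_rate = 1000))$samples
  cx <- as_complexes(list(s, s, s), 1000)
  avg <- ensemble_average(accept_all_report(cx), cx)
  expect_equal(avg$samples, s)

  e <- sin(seq_along(s) / 5)
  cx2 <- as_complexes(list(s + e, s - e), 1000)
  avg2 <- ensemble_average(accept_all_report(cx2), cx2)
  expect_equal(avg2$samples, s)

  # zero accepted -> insufficient-data error advising a lower CF
  rep0 <- accept_all_report(cx)
  rep0$accepted <- FALSE
  err <- expect_error(ensemble_average(rep0, cx),
                      class = "cardiofp_insufficient_data")
  expect_match(conditionMessage(err), "CF")
})

test_that("lag-aware averaging re-aligns shifted complexes", {
  s <- synth_complex(quick_cfg(sample_rate = 2000))$samples
  n <- length(s)
  shift <- function(x, k) if (k > 0) c(rep(x[1], k), x[1:(n - k)])
                          else if (k < 0) c(x[(1 - k):n], rep(x[n], -k))
                          else x
  shifts <- c(0, 3, -2, 5)
  cx <- as_complexes(lapply(shifts, function(k) shift(s, k)), 2000)
  rep_ <- classify_complexes(cx, cx[1, ], cf = 0.9, max_lag = 8)
  expect_equal(rep_$best_lag, -shifts)
  avg <- ensemble_average(rep_, cx)
  lo <- 1 + max(0, max(-shifts))
  hi <- n + min(0, min(-shifts))
  expect_equal(avg$samples, s[lo:hi], tolerance = 1e-10)
})

test_that("alignment jitter of 1 ms low-passes the average", {
  # uniform +/-1 ms misalignment attenuates 200 Hz more than 50 Hz
  fs <- 8000
  t <- seq(0, 0.25 - 1 / fs, by = 1 / fs)
  comp <- function(f) sin(2 * pi * f * t)
  s <- comp(50) + comp(200)
  set.seed(31)
  jit <- sample(-8:8, 64, replace = TRUE)  # +/-1 ms at 8 kHz
  n <- length(s)
  copies <- lapply(jit, function(k) {
    i <- pmin(pmax(seq_len(n) + k, 1), n)
    s[i]
  })
  cx <- as_complexes(copies, fs)
  avg <- ensemble_average(accept_all_report(cx), cx)$samples
  amp <- function(x, f) {
    i <- 200:(n - 200)
    2 * abs(mean(x[i] * exp(-2i * pi * f * t[i])))
  }
  att50 <- amp(avg, 50) / amp(s, 50)
  att200 <- amp(avg, 200) / amp(s, 200)
  expect_lt(att200, att50)
  expect_lt(att50, 1 + 1e-6)
})
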