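# Chromatogram simulator and class-window templates

test_that("noiseless compound apexes land on the nearest scan", {
  cp <- compound_spec("x", 150, cbind(c(73, 147, 207, 281, 299),
                                      c(1, .8, .5, .3, .2)))
  sim <- simulate_run(list(cp), noise = noise_model(0, 0, 1e6, 0, 0, 0),
                      rt_range = c(100, 200), scan_hz = 5, seed = 1)
  eics <- bin_to_eics(sim$run, 1)
  nonzero <- Filter(function(e) max(e$intensity) > 0, eics)
  expect_length(nonzero, 5L)
  for (e in nonzero) expect_equal(e$rt[which.max(e$intensity)], 150)
})

test_that("the same seed reproduces a bit-identical run", {
  cps <- random_compound_set(5, seed = 11)
  a <- simulate_run(cps, rt_range = c(0, 300), seed = 42)
  b <- simulate_run(cps, rt_range = c(0, 300), seed = 42)
  expect_identical(a$run, b$run)
  expect_identical(a$truth, b$truth)
  c <- simulate_run(cps, rt_range = c(0, 300), seed = 43)
  expect_false(identical(a$run, c$run))
})

test_that("a 30-compound run carries full ground truth and visible bleed", {
  cps <- random_compound_set(30, rt_range = c(0, 300), seed = 7)
  sim <- simulate_run(cps, rt_range = c(0, 300), scan_hz = 5, seed = 7)
  expect_equal(length(unique(sim$truth$compound)), 30L)
  expect_true(all(table(sim$truth$compound) >= 4))
  nm <- noise_model()
  rts <- run_rts(sim$run)
  # bleed on a compound-free noise channel: the late trace sits well above
  # the early trace and keeps climbing towards the run end
  eic <- extract_eic(sim$run, default_noise_channels()[1], tol = 0.4)
  early <- mean(eic[rts > 50 & rts < 150])
  late <- mean(eic[rts > nm$bleed_onset + 20])
  expect_gt(late, early + 5 * nm$shot_noise_sd / sqrt(sum(rts > 270)))
  expect_gt(mean(eic[rts > 290]), mean(eic[rts > 255 & rts < 265]))
})

test_that("apexes outside the RT range are rejected", {
  cp <- compound_spec("x", 500, cbind(73, 1))
  expect_error(simulate_run(list(cp), rt_range = c(0, 300)), "outside")
})

test_that("noiseless EICs reproduce the analytic elution profiles", {
  # independent profile formulas
  gauss <- function(t, mu, fwhm) exp(-0.5 * ((t - mu) / (fwhm / 2.3548200450309493))^2)
  emg <- function(t, mu, fwhm, tau) {
    s <- fwhm / 2.3548200450309493
    z <- s / tau - (t - mu) / s
    h <- exp(0.5 * (s / tau)^2 - (t - mu) / tau) *
      2 * pnorm(-z / sqrt(2) * sqrt(2))
    h / max(h)
  }
  cps <- list(compound_spec("g", 150, cbind(c(73, 147), c(1, .5)),
                            max_intensity = 1e5, fwhm = 1.8),
              compound_spec("e", 200, cbind(c(85, 243), c(1, .4)),
                            max_intensity = 2e5, fwhm = 1.6,
                            shape = "emg", emg_tau = 0.4))
  sim <- simulate_run(cps, noise = noise_model(0, 0, 1e6, 0, 0, 0),
                      rt_range = c(100, 250), scan_hz = 5, seed = 1)
  t <- run_rts(sim$run)
  for (cp in cps) {
    ref <- if (cp$shape == "gaussian") gauss(t, cp$rt_apex, cp$fwhm) else
      emg(t, cp$rt_apex, cp$fwhm, cp$emg_tau)
    for (j in seq_along(cp$mz)) {
      eic <- extract_eic(sim$run, cp$mz[j], tol = 0.4)
      want <- cp$abundance[j] * cp$max_intensity * ref
      expect_lt(sqrt(sum((eic - want)^2) / sum(want^2)), 1e-6)
    }
  }
})

test_that("class templates express their defining geometry", {
  # centred apex stays within 5% of the window centre
  wB <- generate_class_window("B", snr = 100, seed = 1)
  s <- colSums(wB$intensities)
  expect_lte(abs(which.max(s) - 21), 0.05 * 41 + 1)
  # shifted apexes land on the correct side
  sA <- colSums(generate_class_window("A", snr = 100, seed = 2)$intensities)
  sC <- colSums(generate_class_window("C", snr = 100, seed = 2)$intensities)
  expect_lt(which.max(sA), 21 - 0.15 * 41)
  expect_gt(which.max(sC), 21 + 0.15 * 41)
  # noise window: the template checker finds no coherent peak
  wD <- generate_class_window("D", snr = 50, seed = 3)
  expect_equal(check_window_class(wD), "D")
  # merged/shoulder: exactly two smoothed local maxima (brute-force scan)
  for (seed in 1:10) {
    wG <- generate_class_window("G", snr = 100, seed = seed)
    sg <- colSums(wG$intensities)
    sm <- stats::filter(sg, rep(1 / 3, 3))
    sm[is.na(sm)] <- 0
    n_max <- 0L
    for (i in 2:(length(sm) - 1)) {
      if (sm[i] > sm[i - 1] && sm[i] >= sm[i + 1] && sm[i] > 0.2 * max(sm)) {
        n_max <- n_max + 1L
      }
    }
    expect_equal(n_max, 2L)
  }
  expect_error(generate_class_window("H"), "unknown")
})

test_that("the rule-based checker re-derives injected labels at snr >= 50", {
  n <- 0L; ok <- 0L
  for (lab in c("A", "B", "C", "D", "E", "F", "G")) {
    for (i in 1:40) {
      w <- generate_class_window(lab, snr = 50,
                                 seed = 1000L + i * 7L + match(lab, LETTERS))
      n <- n + 1L
      ok <- ok + (check_window_class(w) == lab)
    }
  }
  expect_gte(ok / n, 0.99)
})

test_that("training corpora are balanced and seed-reproducible", {
  corpus <- generate_training_corpus(n_per_class = 2, seed = 5)
  expect_length(corpus$windows, 14L)
  expect_equal(as.integer(table(corpus$labels)), rep(2L, 7))
  again <- generate_training_corpus(n_per_class = 2, seed = 5)
  expect_identical(corpus$windows, again$windows)
  one <- generate_training_corpus(n_per_class = 1, seed = 5)
  expect_length(one$windows, 7L)
})
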