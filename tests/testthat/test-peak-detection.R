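# EIC binning, the two built-in pickers, pseudospectrum grouping

test_that("binning conserves every intensity point", {
  sim <- tiny_run()
  eics <- bin_to_eics(sim$run, 1)
  nonzero <- Filter(function(e) max(e$intensity) > 0, eics)
  expect_length(nonzero, 6L)  # 3 fragments per compound
  tic <- run_tic(sim$run)
  total <- Reduce(`+`, lapply(eics, `[[`, "intensity"))
  expect_equal(total, tic)
  # halving the bin width preserves the apexes
  half <- Filter(function(e) max(e$intensity) > 0, bin_to_eics(sim$run, 0.5))
  expect_length(half, 6L)
  expect_setequal(vapply(half, function(e) e$rt[which.max(e$intensity)], 0),
                  vapply(nonzero, function(e) e$rt[which.max(e$intensity)], 0))
})

test_that("matched filter finds noiseless Gaussians at the injected apex", {
  cp <- compound_spec("x", 150, cbind(73, 1), fwhm = 2)
  sim <- simulate_run(list(cp), noise = noise_model(0, 0, 1e6, 0, 0, 0),
                      rt_range = c(100, 200), scan_hz = 5, seed = 1)
  p <- picker_params("matched_filter",
                     list(fwhm = 2, snthresh = 3, step = 1, max_per_eic = 10))
  pk <- pick_matched_filter(sim$run, p)
  expect_length(pk, 1L)
  expect_lte(abs(pk[[1]]$rt_apex - 150), 0.2)
  expect_lt(pk[[1]]$rt_start, pk[[1]]$rt_apex)
  expect_gt(pk[[1]]$rt_end, pk[[1]]$rt_apex)
})

test_that("matched filter resolves two separated peaks (response oracle)", {
  cps <- list(compound_spec("a", 140, cbind(73, 1), fwhm = 2),
              compound_spec("b", 160, cbind(73, 1), fwhm = 2,
                            max_intensity = 7e4))
  sim <- simulate_run(cps, noise = noise_model(0, 0, 1e6, 0, 0, 0),
                      rt_range = c(100, 200), scan_hz = 5, seed = 1)
  p <- picker_params("matched_filter",
                     list(fwhm = 2, snthresh = 3, step = 1, max_per_eic = 10))
  pk <- pick_matched_filter(sim$run, p)
  expect_length(pk, 2L)
  # independent oracle: convolve the EIC with a second-derivative Gaussian
  # kernel built from scratch and enumerate its positive local maxima
  eic <- extract_eic(sim$run, 73, 0.5)
  dt <- 0.2; sigma <- 2 / 2.3548 / dt
  xs <- -ceiling(4 * sigma):ceiling(4 * sigma)
  kern <- (1 - (xs / sigma)^2) * exp(-0.5 * (xs / sigma)^2)
  n <- length(eic)
  resp <- numeric(n)
  for (i in seq_len(n)) {
    js <- pmin(pmax(i + xs, 1L), n)
    resp[i] <- sum(eic[js] * kern)
  }
  n_max <- sum(vapply(2:(n - 1), function(i) {
    resp[i] > resp[i - 1] && resp[i] >= resp[i + 1] && resp[i] > 0.05 * max(resp)
  }, TRUE))
  expect_equal(length(pk), n_max)
})

test_that("matched filter degenerate inputs behave", {
  sim <- tiny_run()
  flat <- sim$run
  for (i in seq_along(flat$scans)) flat$scans[[i]]$intensity[] <- 0
  p <- picker_params("matched_filter",
                     list(fwhm = 2, snthresh = 3, step = 1, max_per_eic = 10))
  expect_length(pick_matched_filter(flat, p), 0L)
  p2 <- picker_params("matched_filter",
                      list(fwhm = 0.3, snthresh = 3, step = 1, max_per_eic = 10))
  expect_error(pick_matched_filter(sim$run, p2), "sampling resolution")
})

test_that("CWT picker matches scales and rejects mismatched ones", {
  cp <- compound_spec("x", 150, cbind(73, 1), fwhm = 2)
  sim <- simulate_run(list(cp), noise = noise_model(0, 0, 1e6, 0, 0, 0),
                      rt_range = c(100, 200), scan_hz = 5, seed = 1)
  p <- picker_params("cwt", list(peakwidth_min = 1, peakwidth_max = 5,
                                 snthresh = 3, prefilter_k = 3,
                                 prefilter_i = 100, max_per_eic = 10))
  pk <- pick_cwt(sim$run, p)
  expect_length(pk, 1L)
  # reported width within a factor 2 of the injected base width (~4.2 s)
  base_w <- 2 * 2.47 * 2 / 2.3548
  w <- pk[[1]]$rt_end - pk[[1]]$rt_start
  expect_gt(w, base_w / 4)
  expect_lt(w, base_w * 2)
  # scale mismatch: no 20-40 s peaks in a 2 s-wide signal
  p_wide <- picker_params("cwt", list(peakwidth_min = 20, peakwidth_max = 40,
                                      snthresh = 3, prefilter_k = 3,
                                      prefilter_i = 100, max_per_eic = 10))
  expect_length(pick_cwt(sim$run, p_wide), 0L)
  # prefilter gate: trace never reaches prefilter_i
  p_gate <- picker_params("cwt", list(peakwidth_min = 1, peakwidth_max = 5,
                                      snthresh = 3, prefilter_k = 3,
                                      prefilter_i = 1e9, max_per_eic = 10))
  expect_length(pick_cwt(sim$run, p_gate), 0L)
  expect_error(picker_params("cwt", list(peakwidth_min = 5, peakwidth_max = 5,
                                         snthresh = 3, prefilter_k = 3,
                                         prefilter_i = 100, max_per_eic = 10)) |>
                 pick_cwt(run = sim$run), "peakwidth_min")
})

test_that("both pickers fully recover noiseless runs and stay silent elsewhere", {
  cps <- random_compound_set(8, rt_range = c(0, 300), seed = 13)
  sim <- simulate_run(cps, noise = noise_model(0, 0, 1e6, 0, 0, 0),
                      rt_range = c(0, 300), scan_hz = 5, seed = 13)
  truth <- unique(sim$truth[, c("compound", "rt_apex_s")])
  for (alg in c("matched_filter", "cwt")) {
    params <- if (alg == "matched_filter") {
      picker_params(alg, list(fwhm = 2, snthresh = 3, step = 1, max_per_eic = 10))
    } else {
      picker_params(alg, list(peakwidth_min = 1, peakwidth_max = 6, snthresh = 3,
                              prefilter_k = 3, prefilter_i = 100, max_per_eic = 10))
    }
    pk <- group_pseudospectra(run_picker(sim$run, params), rt_tol = 1)
    apex <- vapply(pk, `[[`, 0, "rt_apex")
    hits <- vapply(truth$rt_apex_s, function(a) any(abs(apex - a) <= 0.2 + 1e-9), TRUE)
    expect_true(all(hits), label = paste(alg, "recovery"))
    # nothing reported away from the injected compounds
    expect_true(all(vapply(apex, function(a) {
      any(abs(truth$rt_apex_s - a) < 5)
    }, TRUE)), label = paste(alg, "silence"))
  }
})

test_that("raising snthresh never increases the peak count", {
  runs <- acc_opt_runs()
  run <- runs[[1]]
  counts_mf <- vapply(c(2, 5, 10, 20), function(s) {
    length(pick_matched_filter(run, picker_params("matched_filter",
      list(fwhm = 2, snthresh = s, step = 1, max_per_eic = 50))))
  }, 0L)
  expect_true(all(diff(counts_mf) <= 0))
  counts_cwt <- vapply(c(2, 5, 10, 20), function(s) {
    length(pick_cwt(run, picker_params("cwt",
      list(peakwidth_min = 1, peakwidth_max = 6, snthresh = s,
           prefilter_k = 3, prefilter_i = 100, max_per_eic = 50))))
  }, 0L)
  expect_true(all(diff(counts_cwt) <= 0))
})

test_that("pseudospectrum grouping merges co-eluting hits and is idempotent", {
  hits <- lapply(c(599.8, 599.9, 600.0, 600.1, 600.2), function(rt) {
    gc_peak("matched_filter", "s1", rt, rt - 2, rt + 2,
            mz = round(runif(1, 50, 300)) + rt, height = 100)
  })
  g <- group_pseudospectra(hits, rt_tol = 1)
  expect_length(g, 1L)
  expect_length(g[[1]]$mz, 5L)
  far <- list(make_peak(100, 73), make_peak(110, 73))
  expect_length(group_pseudospectra(far, rt_tol = 1), 2L)
  # grouped output equals the connected components of the proximity graph
  set.seed(99)
  apexes <- sort(runif(40, 0, 120))
  hits2 <- lapply(seq_along(apexes), function(i) {
    gc_peak("cwt", "s1", apexes[i], apexes[i] - 1, apexes[i] + 1,
            mz = 50 + i, height = 10)
  })
  g2 <- group_pseudospectra(hits2, rt_tol = 1.5)
  comp <- oracle_components(length(apexes), function(a, b) {
    abs(apexes[a] - apexes[b]) <= 1.5
  })
  expect_length(g2, length(unique(comp)))
  # idempotence
  g3 <- group_pseudospectra(g2, rt_tol = 1.5)
  expect_equal(length(g3), length(g2))
  expect_equal(vapply(g3, `[[`, 0, "rt_apex"), vapply(g2, `[[`, 0, "rt_apex"))
})

test_that("the picker registry validates parameters and accepts plug-ins", {
  expect_setequal(list_pickers(), c("matched_filter", "cwt"))
  expect_error(picker_params("matched_filter", list(fwhm = 2)), "missing")
  expect_error(picker_params("matched_filter",
                             list(fwhm = 2, snthresh = 3, step = 1,
                                  max_per_eic = 10, bogus = 1)), "unknown")
  expect_error(picker_params("matched_filter",
                             list(fwhm = 1e9, snthresh = 3, step = 1,
                                  max_per_eic = 10)), "range")
  register_picker("stub", function(run, params) list(),
                  schema = list(k = c(0, 1)))
  expect_true("stub" %in% list_pickers())
  expect_length(run_picker(tiny_run()$run, picker_params("stub", list(k = 0.5))), 0L)
})
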