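# Window extraction, preprocessing, SVM training and classification

test_that("window extraction centres the apex and obeys the channel rule", {
  sim <- tiny_run()
  pk <- make_peak(150, c(73, 147, 207), height = c(100, 60, 30))
  w <- extract_window(sim$run, pk, window_s = 8, n_mz = 10, n_t = 41)
  expect_equal(range(w$rt_grid), c(146, 154))
  expect_length(w$rt_grid, 41L)
  # 12 channels truncated to the 10 highest apexes
  pk12 <- make_peak(150, seq(60, 280, by = 20), height = seq(120, 10, by = -10))
  w12 <- extract_window(sim$run, pk12, n_mz = 10)
  expect_equal(nrow(w12$intensities), 10L)
  expect_equal(w12$mz_centers[1:10], seq(60, 240, by = 20))
  # near the run end the right side is zero-filled
  pk_end <- make_peak(248, c(73, 147))
  w_end <- extract_window(sim$run, pk_end, window_s = 8)
  right <- w_end$intensities[, w_end$rt_grid > 250]
  expect_true(all(right == 0))
})

test_that("preprocessing is offset- and scale-invariant and max-normalised", {
  w <- generate_class_window("B", seed = 4)
  v <- preprocess_window(w)
  expect_length(v, 10 * 41)
  expect_equal(max(v), 1.0)
  # per-channel additive constants cancel
  w_off <- w
  w_off$intensities <- w_off$intensities + rep(c(50, 100), length.out = 10)
  expect_equal(preprocess_window(w_off), v, tolerance = 1e-10)
  # global multiplicative scaling cancels
  w_sc <- w
  w_sc$intensities <- w_sc$intensities * 37.5
  expect_equal(preprocess_window(w_sc), v, tolerance = 1e-10)
  # all-zero window maps to all-zero vector
  w0 <- peak_window(matrix(0, 10, 41), mz_centers = 1:10, rt_grid = 1:41)
  expect_true(all(preprocess_window(w0) == 0))
})

test_that("training validates its inputs", {
  corpus <- generate_training_corpus(n_per_class = 3, seed = 8)
  single <- corpus$labels == "B"
  expect_error(train_classifier(corpus$windows[single], corpus$labels[single]),
               ">= 2 classes")
  two <- which(corpus$labels %in% c("B", "D"))
  lab <- corpus$labels[two]
  lab[lab == "D"][2:3] <- "B"  # leave one lone D
  expect_error(suppressWarnings(train_classifier(corpus$windows[two], lab)),
               "D")
  w <- capture_warnings(train_classifier(corpus$windows[two], corpus$labels[two]))
  expect_match(w, "700", all = FALSE)
  expect_match(w, "smallest class", all = FALSE)
})

test_that("a small balanced corpus trains a self-consistent classifier", {
  corpus <- generate_training_corpus(n_per_class = 15, seed = 2, snr = 50)
  clf <- suppressWarnings(train_classifier(corpus$windows, corpus$labels,
                                           "matched_filter", seed = 1))
  expect_s3_class(clf, "peak_classifier")
  # training-set accuracy: separable templates must be nearly memorised
  pred <- predict(clf, corpus$windows)
  expect_gte(mean(as.character(pred) == corpus$labels), 0.95)
  # duplicating every window must not change the chosen hyper-parameters
  clf2 <- suppressWarnings(train_classifier(
    c(corpus$windows, corpus$windows), c(corpus$labels, corpus$labels),
    "matched_filter", seed = 1))
  expect_equal(clf2$best$cost, clf$best$cost)
  expect_equal(clf2$best$gamma, clf$best$gamma)
  # prediction on fresh template windows
  wB <- generate_class_window("B", snr = 200, seed = 123)
  wD <- generate_class_window("D", snr = 200, seed = 124)
  expect_equal(as.character(predict(clf, wB)), "B")
  expect_equal(as.character(predict(clf, wD)), "D")
})

test_that("classify_peaks labels peaks in order and checks the algorithm", {
  sim <- tiny_run()
  clf <- small_classifier()
  params <- picker_params("matched_filter",
                          list(fwhm = 2, snthresh = 3, step = 1, max_per_eic = 10))
  pk <- group_pseudospectra(pick_matched_filter(sim$run, params), rt_tol = 1)
  out <- classify_peaks(clf, pk, sim$run)
  expect_length(out, length(pk))
  expect_equal(vapply(out, `[[`, 0, "rt_apex"), vapply(pk, `[[`, 0, "rt_apex"))
  expect_true(all(vapply(out, `[[`, "", "class_label") %in% LETTERS[1:7]))
  # noiseless well-formed compounds are centred high-quality peaks
  expect_true(all(vapply(out, `[[`, "", "class_label") == "B"))
  wrong <- pk
  for (i in seq_along(wrong)) wrong[[i]]$algorithm <- "cwt"
  expect_error(classify_peaks(clf, wrong, sim$run), "cwt")
  expect_length(classify_peaks(clf, list(), sim$run), 0L)
})

test_that("confusion matrices conserve test counts and flag training overlap", {
  corpus <- generate_training_corpus(n_per_class = 15, seed = 2, snr = 50)
  clf <- small_classifier()
  test_set <- generate_training_corpus(n_per_class = 5, seed = 77, snr = 50)
  cm <- evaluate_classifier(clf, test_set$windows, test_set$labels)
  expect_equal(dim(cm), c(7L, 7L))
  expect_equal(unname(rowSums(cm)), rep(5, 7))
  expect_equal(sum(cm), 35)
  mr <- misclassification_rates(cm)
  expect_equal(unname(mr), unname(1 - diag(cm) / rowSums(cm)))
  # perfect predictions give a diagonal matrix on separable templates
  expect_error(evaluate_classifier(clf, corpus$windows[1:3], corpus$labels[1:3]),
               "training")
})

test_that("training-peak sampling is deterministic and warns when starved", {
  sim1 <- tiny_run(seed = 3, sample_id = "qc1")
  sim2 <- tiny_run(seed = 4, sample_id = "qc2")
  grids <- list(matched_filter = list(
    picker_params("matched_filter", list(fwhm = 1, snthresh = 3, step = 1,
                                         max_per_eic = 10)),
    picker_params("matched_filter", list(fwhm = 3, snthresh = 5, step = 1,
                                         max_per_eic = 10))))
  expect_warning(
    res <- sample_training_peaks(list(sim1$run, sim2$run), grids,
                                 n_target = 50, seed = 9),
    "candidate")
  expect_gt(length(res$windows), 0L)
  expect_equal(nrow(res$meta), length(res$windows))
  res2 <- suppressWarnings(sample_training_peaks(list(sim1$run, sim2$run),
                                                 grids, n_target = 50, seed = 9))
  expect_identical(res$meta, res2$meta)
})

test_that("annotation sheets export one image and one template row per window", {
  corpus <- generate_training_corpus(n_per_class = 1, seed = 6)
  dir <- withr::local_tempdir()
  tpl <- export_annotation_sheet(corpus$windows, dir)
  expect_length(list.files(dir, pattern = "\\.png$"), 7L)
  d <- read.csv(tpl)
  expect_equal(nrow(d), 7L)
  # re-export is idempotent: same ids, same template
  export_annotation_sheet(corpus$windows, dir)
  expect_identical(read.csv(tpl), d)
  # labels outside A-G are rejected on re-import
  d$label <- "H"
  write.csv(d, file.path(dir, "labels.csv"), row.names = FALSE)
  expect_error(read_label_file(file.path(dir, "labels.csv")), "A-G")
})
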