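#' Construct a peak window
#'
#' The apex-centred intensity matrix (m/z channels by time points) that the
#' quality classifier consumes.
#'
#' @param intensities `n_mz x n_t` non-negative matrix.
#' @param mz_centers channel m/z values (length `n_mz`; `NA` for padding).
#' @param rt_grid column retention times (length `n_t`).
#' @param source optional [gc_peak()] the window was extracted around.
#' @return an object of class `"peak_window"`.
#' @export
peak_window <- function(intensities, mz_centers, rt_grid, source = NULL) {
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != length(mz_centers)) {
    stopf("mz_centers length (%d) != number of rows (%d)",
          length(mz_centers), nrow(intensities))
  }
  if (ncol(intensities) != length(rt_grid)) {
    stopf("rt_grid length (%d) != number of columns (%d)",
          length(rt_grid), ncol(intensities))
  }
  if (any(intensities < 0)) stopf("window intensities must be >= 0")
  structure(list(intensities = intensities, mz_centers = mz_centers,
                 rt_grid = rt_grid, source = source),
            class = "peak_window")
}

#' Extract the classifier window around a detected peak
#'
#' The window is centred on the apex, spans `window_s` seconds, and is
#' resampled to `n_t` columns by linear interpolation; columns outside the
#' run are zero-filled (border windows are legal: they are class-F
#' candidates). Channels are the peak's m/z channels by descending apex
#' height, padded with zero channels or truncated to `n_mz`.
#'
#' @param run the [raw_run()] the peak came from.
#' @param peak a [gc_peak()].
#' @param window_s window span (s); default 8, twice the typical 4 s full
#'   peak width, so wide-margin and truncated geometries are expressible.
#' @param n_mz,n_t window dimensions.
#' @param mz_tol half-width (Th) used to pull each channel's trace.
#' @return a `peak_window`.
#' @export
extract_window <- function(run, peak, window_s = 8, n_mz = 10, n_t = 41,
                           mz_tol = 0.5) {
  grid <- seq(peak$rt_apex - window_s / 2, peak$rt_apex + window_s / 2,
              length.out = n_t)
  o <- order(peak$height, decreasing = TRUE)
  keep <- o[seq_len(min(n_mz, length(o)))]
  mz_sel <- peak$mz[keep]
  rts <- run_rts(run)
  m <- matrix(0, n_mz, n_t)
  for (i in seq_along(mz_sel)) {
    tr <- extract_eic(run, mz_sel[i], tol = mz_tol)
    m[i, ] <- stats::approx(rts, tr, xout = grid, method = "linear",
                            yleft = 0, yright = 0)$y
  }
  peak_window(m, mz_centers = c(mz_sel, rep(NA_real_, n_mz - length(mz_sel))),
              rt_grid = grid, source = peak)
}

#' Preprocess a window into a classifier feature vector
#'
#' Per channel, a linear baseline through the means of the first and last
#' 10 percent of columns is subtracted and the result clipped at zero; the
#' whole window is then scaled by its global maximum (an all-zero window
#' maps to all zeros) and flattened row-major to length `n_mz * n_t`. The
#' result is invariant to per-channel additive offsets and to global
#' rescaling.
#'
#' @param window a `peak_window`.
#' @return numeric feature vector of length `n_mz * n_t`.
#' @export
preprocess_window <- function(window) {
  m <- window$intensities
  n_t <- ncol(m)
  k <- max(1L, floor(0.1 * n_t))
  i1 <- seq_len(k); i2 <- (n_t - k + 1L):n_t
  x1 <- mean(i1); x2 <- mean(i2)
  for (r in seq_len(nrow(m))) {
    b1 <- mean(m[r, i1]); b2 <- mean(m[r, i2])
    slope <- (b2 - b1) / (x2 - x1)
    m[r, ] <- m[r, ] - (b1 + slope * (seq_len(n_t) - x1))
  }
  m[m < 0] <- 0
  mx <- max(m)
  if (mx > 0) m <- m / mx
  as.vector(t(m))
}

#' Sample a representative training peak set
#'
#' Pools detected peaks from every (picker, parameter set) cell over the
#' given runs, deduplicates per algorithm on apexes within 1 s, stratifies
#' over RT deciles and down-samples uniformly to `n_target`. Deterministic
#' given `seed`. Intended for pooled or quality-control samples.
#'
#' @param runs list of [raw_run()].
#' @param grids named list: algorithm id -> list of [picker_params()].
#' @param n_target training-set size; 700 is the recommended minimum.
#' @param seed integer seed.
#' @param rt_tol dedup apex tolerance (s).
#' @param window_s,n_mz,n_t window geometry passed to [extract_window()].
#' @return list with `windows`, and `meta` (data frame: window_id,
#'   algorithm, sample_id, rt_apex).
#' @export
sample_training_peaks <- function(runs, grids, n_target = 700, seed = 1,
                                  rt_tol = 1, window_s = 8, n_mz = 10,
                                  n_t = 41) {
  cand <- list()
  for (alg in names(grids)) {
    pool <- list()
    for (run in runs) {
      for (params in grids[[alg]]) {
        pk <- group_pseudospectra(run_picker(run, params), rt_tol = rt_tol)
        pool <- c(pool, pk)
      }
    }
    if (!length(pool)) next
    # dedup on apex within rt_tol per sample (single linkage)
    bysmp <- split(pool, vapply(pool, `[[`, "", "sample_id"))
    for (sp in bysmp) {
      apex <- vapply(sp, `[[`, 0, "rt_apex")
      o <- order(apex)
      grp <- cumsum(c(1L, as.integer(diff(apex[o]) > rt_tol)))
      reps <- vapply(split(o, grp), function(idx) {
        idx[which.max(vapply(sp[idx], function(p) sum(p$height), 0))]
      }, 0L)
      cand <- c(cand, sp[reps])
    }
  }
  if (!length(cand)) stopf("no candidate peaks detected on the training runs")
  run_lookup <- stats::setNames(runs, vapply(runs, `[[`, "", "sample_id"))
  apex <- vapply(cand, `[[`, 0, "rt_apex")
  breaks <- unique(stats::quantile(apex, seq(0, 1, 0.1)))
  stratum <- if (length(breaks) < 2L) {
    rep(1L, length(apex))
  } else {
    as.integer(cut(apex, breaks, include.lowest = TRUE, labels = FALSE))
  }
  sel <- with_seed(seed, {
    if (length(cand) <= n_target) {
      if (length(cand) < n_target) {
        warnf("only %d candidate peaks available (requested %d); returning all",
              length(cand), n_target)
      }
      seq_along(cand)
    } else {
      per <- ceiling(n_target / 10)
      idx <- unlist(lapply(split(seq_along(cand), stratum), function(ii) {
        sample(ii, min(per, length(ii)))
      }))
      if (length(idx) > n_target) idx <- sort(sample(idx, n_target))
      sort(idx)
    }
  })
  chosen <- cand[sel]
  windows <- vector("list", length(chosen))
  meta <- data.frame(window_id = character(length(chosen)),
                     algorithm = "", sample_id = "", rt_apex = 0,
                     stringsAsFactors = FALSE)
  for (i in seq_along(chosen)) {
    p <- chosen[[i]]
    w <- extract_window(run_lookup[[p$sample_id]], p, window_s = window_s,
                        n_mz = n_mz, n_t = n_t)
    wid <- sprintf("%s_%s_rt%07.2f", p$algorithm, p$sample_id, p$rt_apex)
    attr(w, "window_id") <- wid
    windows[[i]] <- w
    meta$window_id[i] <- wid
    meta$algorithm[i] <- p$algorithm
    meta$sample_id[i] <- p$sample_id
    meta$rt_apex[i] <- p$rt_apex
  }
  list(windows = windows, meta = meta)
}

#' Export windows for offline labelling
#'
#' Writes one PNG per window (all channels overlaid) plus a CSV label
#' template (`window_id, label`) with blank labels, for manual annotation.
#' Stable ids make re-export idempotent.
#'
#' @param windows list of `peak_window` (with `"window_id"` attributes).
#' @param out_dir output directory (created if needed).
#' @return path of the written template CSV, invisibly.
#' @export
export_annotation_sheet <- function(windows, out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stopf("cannot create directory '%s'", out_dir)
  ids <- vapply(seq_along(windows), function(i) {
    attr(windows[[i]], "window_id") %||% sprintf("w%04d", i)
  }, "")
  for (i in seq_along(windows)) {
    f <- file.path(out_dir, paste0(ids[i], ".png"))
    grDevices::png(f, width = 640, height = 420)
    m <- windows[[i]]$intensities
    graphics::matplot(windows[[i]]$rt_grid, t(m), type = "l", lty = 1,
                      xlab = "RT (s)", ylab = "intensity", main = ids[i])
    grDevices::dev.off()
  }
  tpl <- file.path(out_dir, "labels_template.csv")
  utils::write.csv(data.frame(window_id = ids, label = "",
                              stringsAsFactors = FALSE),
                   tpl, row.names = FALSE, quote = FALSE)
  invisible(tpl)
}

#' Read and validate a label file
#'
#' @param path CSV with columns `window_id, label`; labels must all be one
#'   of `"A"`..`"G"`.
#' @return data frame with validated labels.
#' @export
read_label_file <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("window_id", "label") %in% names(d))) {
    stopf("label file must have columns window_id, label")
  }
  bad <- setdiff(unique(d$label), CLASS_LEVELS)
  if (length(bad)) {
    stopf("invalid label(s) in '%s': %s (must be A-G)", path,
          paste(bad, collapse = ", "))
  }
  d
}

#' Train a seven-class peak-quality SVM
#'
#' Fits a multi-class (one-vs-one) RBF-kernel support vector machine on
#' preprocessed window vectors, selecting `(C, gamma)` over a log grid by
#' 5-fold stratified cross-validation. Exact duplicate windows are dropped
#' before training so they cannot leak across CV folds. One classifier is
#' trained per picker algorithm. Deterministic given `seed`.
#'
#' @param windows list of `peak_window`.
#' @param labels character vector of class labels, one per window.
#' @param algorithm_id picker id this classifier belongs to.
#' @param seed integer seed for fold assignment.
#' @param cost_grid,gamma_grid hyper-parameter candidates.
#' @param n_folds stratified CV folds.
#' @param training_samples optional sample ids the windows came from
#'   (recorded so the optimiser can warn about training/optimisation
#'   sample overlap).
#' @return an object of class `"peak_classifier"` with the fitted model,
#'   recorded preprocessing parameters and a `cv_report`.
#' @export
train_classifier <- function(windows, labels, algorithm_id = "generic",
                             seed = 1,
                             cost_grid = c(0.1, 1, 10, 100),
                             gamma_grid = 10^seq(-4, 0),
                             n_folds = 5, training_samples = NULL) {
  if (length(windows) != length(labels)) {
    stopf("windows and labels lengths differ")
  }
  bad <- setdiff(unique(labels), CLASS_LEVELS)
  if (length(bad)) stopf("unknown label(s): %s", paste(bad, collapse = ", "))
  tab <- table(factor(labels, levels = CLASS_LEVELS))
  present <- names(tab)[tab > 0]
  if (length(present) < 2L) stopf("training needs >= 2 classes (got %d)",
                                  length(present))
  small <- names(tab)[tab == 1L]
  if (length(small)) stopf("class(es) with < 2 members: %s",
                           paste(small, collapse = ", "))
  if (length(labels) < 700L) {
    warnf("training set has %d windows; >= 700 labelled peaks are recommended",
          length(labels))
  }
  if (min(tab[tab > 0]) < 7L) {
    warnf("smallest class has %d windows; >= 7 are recommended", min(tab[tab > 0]))
  }
  n_mz <- nrow(windows[[1]]$intensities); n_t <- ncol(windows[[1]]$intensities)
  X <- t(vapply(windows, preprocess_window, numeric(n_mz * n_t)))
  # exact duplicate windows carry no information and would leak across CV
  # folds, distorting hyper-parameter selection; drop them up front
  dup <- duplicated(X)
  if (any(dup)) {
    X <- X[!dup, , drop = FALSE]
    labels <- labels[!dup]
    windows <- windows[!dup]
  }
  y <- factor(labels, levels = CLASS_LEVELS)
  yd <- droplevels(y)
  folds <- with_seed(seed, {
    f <- integer(length(yd))
    for (cl in levels(yd)) {
      idx <- sample(which(yd == cl))
      f[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    f
  })
  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid)
  acc <- matrix(NA_real_, nrow(grid), n_folds)
  for (g in seq_len(nrow(grid))) {
    for (k in seq_len(n_folds)) {
      tr <- folds != k
      if (!any(!tr) || length(unique(yd[tr])) < 2L) next
      fit <- e1071::svm(X[tr, , drop = FALSE], yd[tr], kernel = "radial",
                        cost = grid$cost[g], gamma = grid$gamma[g],
                        scale = FALSE)
      pr <- stats::predict(fit, X[!tr, , drop = FALSE])
      acc[g, k] <- mean(pr == yd[!tr])
    }
  }
  mean_acc <- rowMeans(acc, na.rm = TRUE)
  best <- order(-mean_acc, grid$cost, grid$gamma)[1L]
  model <- e1071::svm(X, yd, kernel = "radial", cost = grid$cost[best],
                      gamma = grid$gamma[best], scale = FALSE)
  cv_report <- cbind(grid, mean_accuracy = mean_acc,
                     as.data.frame(acc) |>
                       stats::setNames(paste0("fold", seq_len(n_folds))))
  ids <- vapply(seq_along(windows), function(i) {
    attr(windows[[i]], "window_id") %||% NA_character_
  }, "")
  structure(list(
    algorithm_id = algorithm_id, model = model,
    preprocessing = list(n_mz = n_mz, n_t = n_t, window_s = diff(range(windows[[1]]$rt_grid)),
                         baseline = "two-anchor linear (first/last 10% of columns)",
                         scaling = "global maximum"),
    cv_report = cv_report,
    best = list(cost = grid$cost[best], gamma = grid$gamma[best],
                cv_accuracy = mean_acc[best]),
    levels = CLASS_LEVELS, trained_levels = levels(yd),
    training_ids = ids[!is.na(ids)],
    training_samples = training_samples %||% character(0),
    seed = seed), class = "peak_classifier")
}

#' @export
print.peak_classifier <- function(x, ...) {
  cat(sprintf("<peak_classifier> for picker '%s'\n", x$algorithm_id))
  cat(sprintf("  window: %d m/z x %d points over %.1f s; %s baseline, %s scaling\n",
              x$preprocessing$n_mz, x$preprocessing$n_t, x$preprocessing$window_s,
              x$preprocessing$baseline, x$preprocessing$scaling))
  cat(sprintf("  RBF SVM (one-vs-one), C = %g, gamma = %g; CV accuracy %.3f over %d windows\n",
              x$best$cost, x$best$gamma, x$best$cv_accuracy,
              length(x$training_ids)))
  invisible(x)
}

#' @export
summary.peak_classifier <- function(object, ...) {
  print(object)
  cat("\nCross-validation grid (top 5 by accuracy):\n")
  o <- order(-object$cv_report$mean_accuracy)
  print(utils::head(object$cv_report[o, c("cost", "gamma", "mean_accuracy")], 5),
        row.names = FALSE)
  invisible(object$cv_report)
}

#' @export
predict.peak_classifier <- function(object, windows, ...) {
  if (inherits(windows, "peak_window")) windows <- list(windows)
  if (!length(windows)) return(factor(character(0), levels = CLASS_LEVELS))
  nf <- object$preprocessing$n_mz * object$preprocessing$n_t
  X <- t(vapply(windows, preprocess_window, numeric(nf)))
  pr <- stats::predict(object$model, X)
  factor(as.character(pr), levels = CLASS_LEVELS)
}

#' Classify detected peaks
#'
#' Extracts and preprocesses the classifier window around every peak and
#' assigns one of the seven quality classes. Input order is preserved.
#'
#' @param classifier a `peak_classifier` whose `algorithm_id` matches every
#'   peak's algorithm.
#' @param peaks list of [gc_peak()].
#' @param runs a [raw_run()] or named list of runs keyed by sample id.
#' @return the peaks, with `class_label` set.
#' @export
classify_peaks <- function(classifier, peaks, runs) {
  if (!length(peaks)) return(peaks)
  if (inherits(runs, "raw_run")) {
    runs <- stats::setNames(list(runs), runs$sample_id)
  }
  algs <- unique(vapply(peaks, `[[`, "", "algorithm"))
  if (!all(algs == classifier$algorithm_id)) {
    stopf("classifier for '%s' applied to peaks from '%s'",
          classifier$algorithm_id, paste(setdiff(algs, classifier$algorithm_id),
                                         collapse = ", "))
  }
  pp <- classifier$preprocessing
  windows <- lapply(peaks, function(p) {
    run <- runs[[p$sample_id]]
    if (is.null(run)) stopf("no run supplied for sample '%s'", p$sample_id)
    extract_window(run, p, window_s = pp$window_s, n_mz = pp$n_mz, n_t = pp$n_t)
  })
  lab <- as.character(predict(classifier, windows))
  for (i in seq_along(peaks)) peaks[[i]]$class_label <- lab[i]
  peaks
}

#' Evaluate a classifier on held-out windows
#'
#' @param classifier a `peak_classifier`.
#' @param windows held-out `peak_window` list (disjoint from training; window
#'   ids shared with the training set raise an error).
#' @param labels true labels.
#' @return 7x7 confusion matrix (rows = true, columns = predicted), class
#'   `"confusion_matrix"`.
#' @export
evaluate_classifier <- function(classifier, windows, labels) {
  ids <- vapply(seq_along(windows), function(i) {
    attr(windows[[i]], "window_id") %||% NA_character_
  }, "")
  shared <- intersect(ids[!is.na(ids)], classifier$training_ids)
  if (length(shared)) {
    stopf("%d test window(s) were part of the training set (e.g. %s)",
          length(shared), shared[1])
  }
  pred <- predict(classifier, windows)
  cm <- table(true = factor(labels, levels = CLASS_LEVELS), predicted = pred)
  structure(unclass(cm), class = c("confusion_matrix", "table"))
}

#' Per-class misclassification rates of a confusion matrix
#'
#' @param cm a `confusion_matrix`.
#' @return named numeric vector, `1 - diagonal / row sum` per class (NA for
#'   empty classes).
#' @export
misclassification_rates <- function(cm) {
  rs <- rowSums(cm)
  r <- 1 - diag(cm) / rs
  r[rs == 0] <- NA_real_
  r
}
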