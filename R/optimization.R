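#' Class-weight vector for the parameter score
#'
#' The score rewards high-quality peaks and penalises noise and
#' intermediate-quality peaks. Defaults: +1 for A/B/C, -1 for D (noise),
#' -0.5 for E/F/G. Weights are freely user-definable, subject to at least
#' one positive high-quality weight and a non-positive noise weight.
#'
#' @param A,B,C,D,E,F,G per-class weights.
#' @return named numeric vector of class `"score_weights"`.
#' @export
score_weights <- function(A = 1, B = 1, C = 1, D = -1,
                          E = -0.5, F = -0.5, G = -0.5) {
  w <- c(A = A, B = B, C = C, D = D, E = E, F = F, G = G)
  if (max(w[HIGH_CLASSES]) <= 0) {
    stopf("at least one high-quality weight (A/B/C) must be > 0")
  }
  if (w["D"] > 0) stopf("the noise weight w_D must be <= 0")
  structure(w, class = "score_weights")
}

#' Count peaks per quality class
#'
#' @param peaks list of classified [gc_peak()].
#' @return named integer vector `n_A`..`n_G` (names `A`..`G`).
#' @export
class_counts <- function(peaks) {
  lab <- vapply(peaks, `[[`, "", "class_label")
  if (anyNA(lab)) stopf("all peaks must be classified before counting")
  tab <- table(factor(lab, levels = CLASS_LEVELS))
  stats::setNames(as.integer(tab), CLASS_LEVELS)
}

#' Linear class-weighted score
#'
#' `S = sum over classes of w_c * n_c`.
#'
#' @param counts named vector of per-class counts (names `A`..`G`).
#' @param weights a [score_weights()].
#' @return scalar score.
#' @export
score_counts <- function(counts, weights = score_weights()) {
  if (any(counts < 0)) stopf("class counts must be >= 0")
  sum(as.double(weights[CLASS_LEVELS]) *
        as.double(counts[CLASS_LEVELS]))
}

#' Expand a parameter grid for a picker
#'
#' @param algorithm registered picker id.
#' @param ranges named list of candidate values per varied parameter;
#'   parameters not listed take the values in `fixed`.
#' @param fixed named list of fixed parameter values.
#' @return list of [picker_params()], one per Cartesian grid point.
#' @export
expand_param_grid <- function(algorithm, ranges, fixed = list()) {
  schema <- picker_grid_schema(algorithm)
  all_named <- c(names(ranges), names(fixed))
  missing <- setdiff(names(schema), all_named)
  if (length(missing)) {
    stopf("picker '%s': no values for parameter(s) %s", algorithm,
          paste(missing, collapse = ", "))
  }
  g <- expand.grid(ranges, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(g)), function(i) {
    vals <- c(as.list(g[i, , drop = FALSE]), fixed)
    picker_params(algorithm, vals[names(schema)])
  })
}

#' Grid search for optimal picker parameters
#'
#' For every grid point: pick, group into pseudospectra, classify, count per
#' class, and score; counts are summed over the optimisation runs. The best
#' point is the score argmax; ties are broken by fewest class-D peaks, then
#' by lexicographic parameter order, so the result is deterministic.
#'
#' @param algorithm registered picker id.
#' @param grid list of [picker_params()] (e.g. from [expand_param_grid()]).
#' @param runs list of [raw_run()] optimisation samples (use at least two,
#'   disjoint from the classifier's training samples; overlap warns).
#' @param classifier the picker's `peak_classifier`.
#' @param weights a [score_weights()].
#' @param rt_tol pseudospectrum grouping tolerance (s).
#' @return an object of class `"optimization_result"`: `per_combination`
#'   data frame (parameters, `n_A`..`n_G`, `total`, `score`), `best`
#'   ([picker_params()]) and `best_score`.
#' @export
grid_search <- function(algorithm, grid, runs, classifier,
                        weights = score_weights(), rt_tol = 1) {
  if (!length(grid)) stopf("empty parameter grid")
  if (length(runs) < 2L) {
    warnf("parameter optimisation with a single run; >= 2 runs are recommended")
  }
  opt_samples <- vapply(runs, `[[`, "", "sample_id")
  overlap <- intersect(opt_samples, classifier$training_samples)
  if (length(overlap)) {
    warnf("optimisation run(s) %s also used for classifier training",
          paste(overlap, collapse = ", "))
  }
  run_lookup <- stats::setNames(runs, opt_samples)
  pnames <- names(grid[[1]]$values)
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    params <- grid[[i]]
    counts <- stats::setNames(integer(7), CLASS_LEVELS)
    for (run in runs) {
      pk <- group_pseudospectra(run_picker(run, params), rt_tol = rt_tol)
      pk <- classify_peaks(classifier, pk, run_lookup)
      if (length(pk)) counts <- counts + class_counts(pk)
    }
    rows[[i]] <- c(unlist(params$values), counts)
  }
  per <- as.data.frame(do.call(rbind, rows))
  names(per) <- c(pnames, paste0("n_", CLASS_LEVELS))
  per$grid_id <- vapply(grid, `[[`, "", "grid_id")
  per$total <- rowSums(per[paste0("n_", CLASS_LEVELS)])
  per$score <- apply(per[paste0("n_", CLASS_LEVELS)], 1L, function(n) {
    score_counts(stats::setNames(n, CLASS_LEVELS), weights)
  })
  best_i <- select_best_index(per, pnames)
  structure(list(algorithm = algorithm,
                 per_combination = per,
                 best = grid[[best_i]],
                 best_score = per$score[best_i],
                 weights = weights),
            class = "optimization_result")
}

# deterministic argmax: highest score, then fewest class-D peaks, then
# lexicographic parameter order
select_best_index <- function(per, pnames) {
  ord <- do.call(order, c(list(-per$score, per$n_D),
                          lapply(pnames, function(p) per[[p]])))
  ord[1L]
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("<optimization_result> picker '%s', %d grid points\n",
              x$algorithm, nrow(x$per_combination)))
  cat(sprintf("  best score %.1f at %s\n", x$best_score, x$best$grid_id))
  invisible(x)
}

#' Write an optimisation result as CSV
#'
#' One row per grid point (parameters, per-class counts, total, score) for
#' heat-map style inspection of the parameter landscape.
#'
#' @param result an `optimization_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_optimization_csv <- function(result, path) {
  utils::write.csv(result$per_combination, path, row.names = FALSE)
  invisible(path)
}
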