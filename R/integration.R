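#' Integration configuration
#'
#' Controls the filtering, duplicate-removal and merging of classified peak
#' sets. Two peaks count as duplicates only when their apexes lie within the
#' RT tolerance AND their fragment spectra agree (binned cosine), so that
#' co-eluting distinct compounds are not collapsed.
#'
#' @param min_mz minimum number of m/z per peak (default 3).
#' @param dedup_rt_tol within-algorithm duplicate apex tolerance (s).
#' @param merge_rt_tol cross-algorithm / cross-sample apex tolerance (s).
#' @param merge_min_spec_sim minimum spectral cosine for duplicates, in
#'   `[0, 1]`.
#' @param class_priority label ordering used to choose the representative of
#'   a duplicate group (first = highest); the default prefers centred apexes
#'   (B), then A/C, then G, E, F, D.
#' @return an object of class `"integration_config"`.
#' @export
integration_config <- function(min_mz = 3, dedup_rt_tol = 2, merge_rt_tol = 2,
                               merge_min_spec_sim = 0.8,
                               class_priority = c("B", "A", "C", "G", "E", "F", "D")) {
  if (min_mz < 1) stopf("min_mz must be >= 1")
  if (dedup_rt_tol <= 0 || merge_rt_tol <= 0) stopf("tolerances must be > 0")
  if (merge_min_spec_sim < 0 || merge_min_spec_sim > 1) {
    stopf("merge_min_spec_sim must lie in [0, 1]")
  }
  if (!setequal(class_priority, CLASS_LEVELS)) {
    stopf("class_priority must be a permutation of A-G")
  }
  structure(list(min_mz = as.integer(min_mz), dedup_rt_tol = dedup_rt_tol,
                 merge_rt_tol = merge_rt_tol,
                 merge_min_spec_sim = merge_min_spec_sim,
                 class_priority = class_priority),
            class = "integration_config")
}

# rank of a label under the config's priority (higher = preferred);
# A and C share a rank under the default ordering
priority_rank <- function(labels, cfg) {
  pr <- rev(cfg$class_priority)
  r <- match(labels, pr)
  if (identical(cfg$class_priority, c("B", "A", "C", "G", "E", "F", "D"))) {
    r[labels %in% c("A", "C")] <- match("C", pr)  # A == C tie
  }
  r
}

#' Reject peaks with too few fragments
#'
#' @param peaks list of [gc_peak()] (already grouped into pseudospectra).
#' @param min_mz minimum fragment count; a peak is kept iff
#'   `length(mz) >= min_mz`. Order is preserved.
#' @return surviving peaks.
#' @export
filter_min_mz <- function(peaks, min_mz = 3) {
  peaks[vapply(peaks, function(p) length(p$mz) >= min_mz, TRUE)]
}

# connected duplicate components under (rt tolerance AND cosine) criterion
duplicate_components <- function(peaks, rt_tol, min_sim) {
  n <- length(peaks)
  if (n <= 1L) return(seq_len(n))
  apex <- vapply(peaks, `[[`, 0, "rt_apex")
  edges <- NULL
  o <- order(apex)
  for (ii in seq_len(n - 1L)) {
    for (jj in (ii + 1L):n) {
      a <- o[ii]; b <- o[jj]
      if (apex[b] - apex[a] > rt_tol) break
      if (peak_cosine(peaks[[a]], peaks[[b]]) >= min_sim) {
        edges <- rbind(edges, c(a, b))
      }
    }
  }
  connected_components(n, edges)
}

# pick the representative of a duplicate group: highest class priority,
# then larger summed apex intensity, then earlier RT
pick_representative <- function(peaks, cfg) {
  lab <- vapply(peaks, `[[`, "", "class_label")
  lab[is.na(lab)] <- "D"
  r <- priority_rank(lab, cfg)
  tot <- vapply(peaks, function(p) sum(p$height), 0)
  apex <- vapply(peaks, `[[`, 0, "rt_apex")
  order(-r, -tot, apex)[1L]
}

#' Class-based removal of duplicate peaks within one algorithm
#'
#' Among peaks (one sample, one algorithm) whose apexes lie within
#' `dedup_rt_tol` and whose spectra have cosine at least
#' `merge_min_spec_sim`, exactly one is kept: the one with the highest class
#' priority, ties broken by larger summed apex intensity, then earlier RT.
#'
#' @param peaks list of classified [gc_peak()] from one sample and algorithm.
#' @param cfg an [integration_config()].
#' @return deduplicated peaks; the number of collapsed peaks is recorded in
#'   attribute `"n_collapsed"`.
#' @export
dedup_within <- function(peaks, cfg = integration_config()) {
  if (length(peaks) <= 1L) return(structure(peaks, n_collapsed = 0L))
  comp <- duplicate_components(peaks, cfg$dedup_rt_tol, cfg$merge_min_spec_sim)
  kept <- lapply(split(seq_along(peaks), comp), function(idx) {
    peaks[[idx[pick_representative(peaks[idx], cfg)]]]
  })
  kept <- kept[order(vapply(kept, `[[`, 0, "rt_apex"))]
  structure(kept, n_collapsed = length(peaks) - length(kept))
}

#' Merge per-algorithm peak sets
#'
#' Pools the (already deduplicated) per-algorithm sets of one sample and
#' collapses cross-algorithm duplicates under the same RT + spectral
#' similarity criterion; the representative is chosen by the same priority
#' rule, and each merged feature's provenance lists every contributing
#' algorithm. Non-overlapping peaks pass through unchanged.
#'
#' @param per_algorithm_sets list of peak lists, one per algorithm.
#' @param cfg an [integration_config()].
#' @return merged peaks with provenance; collapsed count in attribute
#'   `"n_collapsed"`.
#' @export
merge_across <- function(per_algorithm_sets, cfg = integration_config()) {
  pool <- do.call(c, per_algorithm_sets) %||% list()
  if (length(pool) <= 1L) return(structure(pool, n_collapsed = 0L))
  comp <- duplicate_components(pool, cfg$merge_rt_tol, cfg$merge_min_spec_sim)
  merged <- lapply(split(seq_along(pool), comp), function(idx) {
    rep_i <- idx[pick_representative(pool[idx], cfg)]
    p <- pool[[rep_i]]
    p$provenance$algorithms <-
      sort(unique(unlist(lapply(pool[idx], function(q) q$provenance$algorithms))))
    p$provenance$source_ids <-
      sort(unique(stats::na.omit(c(p$provenance$source_ids,
                                   vapply(pool[idx], `[[`, "", "id")))))
    p
  })
  merged <- merged[order(vapply(merged, `[[`, 0, "rt_apex"))]
  structure(merged, n_collapsed = length(pool) - length(merged))
}

#' Partition classified peaks by quality tier
#'
#' @param peaks list of classified [gc_peak()].
#' @return list with `high` (classes A/B/C), `review` (E/F/G) and `noise`
#'   (D); the three partitions are disjoint and jointly exhaustive.
#' @export
partition_by_class <- function(peaks) {
  lab <- vapply(peaks, `[[`, "", "class_label")
  if (anyNA(lab)) {
    stopf("%d unlabelled peak(s); classify before partitioning", sum(is.na(lab)))
  }
  list(high = peaks[lab %in% HIGH_CLASSES],
       review = peaks[lab %in% REVIEW_CLASSES],
       noise = peaks[lab %in% NOISE_CLASS])
}

#' Filter, deduplicate, merge and partition classified peaks
#'
#' Runs the full integration chain for one sample: the minimum-m/z filter
#' and class-based duplicate removal per algorithm, the cross-algorithm
#' merge, and the quality partition. Conservation accounting is kept: every
#' input peak ends up in exactly one of high / review / noise /
#' dropped-by-min-mz / collapsed-as-duplicate.
#'
#' @param per_algorithm_sets named list: algorithm id -> list of classified
#'   [gc_peak()] from one sample.
#' @param cfg an [integration_config()].
#' @return an object of class `"final_peak_set"` with partitions `high`,
#'   `review`, `noise` and an `accounting` vector.
#' @export
integrate_peaks <- function(per_algorithm_sets, cfg = integration_config()) {
  n_input <- sum(lengths(per_algorithm_sets))
  filtered <- lapply(per_algorithm_sets, filter_min_mz, min_mz = cfg$min_mz)
  n_dropped <- n_input - sum(lengths(filtered))
  deduped <- lapply(filtered, dedup_within, cfg = cfg)
  n_dupes <- sum(vapply(deduped, function(x) attr(x, "n_collapsed") %||% 0L, 0L))
  merged <- merge_across(deduped, cfg)
  n_dupes <- n_dupes + (attr(merged, "n_collapsed") %||% 0L)
  parts <- partition_by_class(merged)
  structure(list(high = parts$high, review = parts$review, noise = parts$noise,
                 accounting = c(input = n_input,
                                dropped_min_mz = n_dropped,
                                collapsed_duplicates = n_dupes,
                                high = length(parts$high),
                                review = length(parts$review),
                                noise = length(parts$noise)),
                 cfg = cfg), class = "final_peak_set")
}

#' @export
print.final_peak_set <- function(x, ...) {
  a <- x$accounting
  cat(sprintf("<final_peak_set> %d input peaks -> %d high / %d review / %d noise (%d dropped by min m/z, %d duplicates collapsed)\n",
              a["input"], a["high"], a["review"], a["noise"],
              a["dropped_min_mz"], a["collapsed_duplicates"]))
  invisible(x)
}

#' Align features across samples into a feature table
#'
#' Greedy clustering seeded from the most intense unassigned feature: every
#' unassigned feature of any sample within `merge_rt_tol` of the seed apex
#' and with spectral cosine at least `merge_min_spec_sim` joins the cluster
#' (at most one feature per sample; the most intense eligible one). Table
#' cells are summed apex heights over the feature's m/z list, with an area
#' variant and a missingness mask alongside (missing = 0).
#'
#' @param per_sample_sets named list: sample id -> list of [gc_peak()]
#'   (typically the `high` partition of each sample's `final_peak_set`).
#' @param cfg an [integration_config()].
#' @return an object of class `"feature_table"`: `features` data frame,
#'   `height` and `area` matrices (feature x sample), `detected` logical
#'   mask and `peaks` (one representative [gc_peak()] per feature).
#' @export
align_across_samples <- function(per_sample_sets, cfg = integration_config()) {
  if (!length(per_sample_sets)) stopf("need at least one sample")
  samples <- names(per_sample_sets)
  if (is.null(samples) || any(samples == "")) {
    stopf("per_sample_sets must be named by sample id")
  }
  pool <- list(); pool_sample <- character(0)
  for (s in samples) {
    pool <- c(pool, per_sample_sets[[s]])
    pool_sample <- c(pool_sample, rep(s, length(per_sample_sets[[s]])))
  }
  n <- length(pool)
  if (!n) {
    return(structure(list(
      features = data.frame(feature_id = character(0), rt_apex_s = numeric(0),
                            n_mz = integer(0), class_label = character(0),
                            ri = numeric(0)),
      height = matrix(0, 0, length(samples), dimnames = list(NULL, samples)),
      area = matrix(0, 0, length(samples), dimnames = list(NULL, samples)),
      detected = matrix(FALSE, 0, length(samples), dimnames = list(NULL, samples)),
      peaks = list(), samples = samples), class = "feature_table"))
  }
  inten <- vapply(pool, function(p) sum(p$height), 0)
  apex <- vapply(pool, `[[`, 0, "rt_apex")
  unassigned <- rep(TRUE, n)
  clusters <- list()
  while (any(unassigned)) {
    seed_i <- which(unassigned)[which.max(inten[unassigned])]
    member <- integer(0)
    for (s in samples) {
      elig <- which(unassigned & pool_sample == s &
                      abs(apex - apex[seed_i]) <= cfg$merge_rt_tol)
      elig <- elig[vapply(elig, function(j) {
        peak_cosine(pool[[seed_i]], pool[[j]]) >= cfg$merge_min_spec_sim
      }, TRUE)]
      if (length(elig)) member <- c(member, elig[which.max(inten[elig])])
    }
    member <- sort(unique(c(seed_i, member)))
    unassigned[member] <- FALSE
    clusters[[length(clusters) + 1L]] <- member
  }
  ord <- order(vapply(clusters, function(m) min(apex[m]), 0))
  clusters <- clusters[ord]
  k <- length(clusters)
  height <- matrix(0, k, length(samples), dimnames = list(NULL, samples))
  area <- matrix(0, k, length(samples), dimnames = list(NULL, samples))
  detected <- matrix(FALSE, k, length(samples), dimnames = list(NULL, samples))
  reps <- vector("list", k)
  for (i in seq_len(k)) {
    m <- clusters[[i]]
    reps[[i]] <- pool[[m[which.max(inten[m])]]]
    for (j in m) {
      s <- pool_sample[j]
      height[i, s] <- sum(pool[[j]]$height)
      area[i, s] <- sum(pool[[j]]$area)
      detected[i, s] <- TRUE
    }
  }
  features <- data.frame(
    feature_id = sprintf("F%04d", seq_len(k)),
    rt_apex_s = vapply(reps, `[[`, 0, "rt_apex"),
    n_mz = vapply(reps, function(p) length(p$mz), 0L),
    class_label = vapply(reps, `[[`, "", "class_label"),
    ri = vapply(reps, function(p) p$ri %||% NA_real_, 0),
    stringsAsFactors = FALSE)
  structure(list(features = features, height = height, area = area,
                 detected = detected, peaks = reps, samples = samples),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d samples (%.0f%% detected)\n",
              nrow(x$features), length(x$samples),
              100 * mean(x$detected)))
  invisible(x)
}

#' Two-group fold changes and p-values
#'
#' Welch's two-sample t-test on `log2(intensity + 1)` per feature. The fold
#' change is the ratio of group means `r = mean(group1) / mean(group2)`,
#' displayed as `r` when `r >= 1` and as `-1/r` otherwise, so a negative
#' value denotes a decrease in group 1. Features where either group is all
#' zero are flagged and not tested.
#'
#' @param table a `feature_table` (heights are used).
#' @param groups named character vector mapping sample id to condition;
#'   exactly 2 conditions with >= 2 samples each.
#' @param p_adjust `"none"` (default; raw p-values) or `"BH"` for
#'   Benjamini-Hochberg correction.
#' @return data frame: `feature_id, fold_change, p_value, flag`.
#' @export
compute_group_stats <- function(table, groups, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  groups <- groups[table$samples]
  if (anyNA(groups)) stopf("every sample needs a group assignment")
  conds <- unique(groups)
  if (length(conds) != 2L) stopf("exactly 2 conditions required (got %d)",
                                 length(conds))
  if (any(table(groups) < 2L)) stopf("each condition needs >= 2 samples")
  s1 <- table$samples[groups == conds[1]]
  s2 <- table$samples[groups == conds[2]]
  k <- nrow(table$features)
  fc <- rep(NA_real_, k); pv <- rep(NA_real_, k); flag <- rep("", k)
  for (i in seq_len(k)) {
    x <- table$height[i, s1]; y <- table$height[i, s2]
    if (all(x == 0) || all(y == 0)) {
      flag[i] <- "zero-only group; not tested"
      next
    }
    r <- mean(x) / mean(y)
    fc[i] <- if (r >= 1) r else -1 / r
    lx <- log2(x + 1); ly <- log2(y + 1)
    pv[i] <- if (stats::var(lx) + stats::var(ly) == 0) {
      if (mean(lx) == mean(ly)) 1 else 0   # degenerate zero-variance case
    } else {
      stats::t.test(lx, ly, var.equal = FALSE)$p.value
    }
  }
  if (p_adjust == "BH") pv <- stats::p.adjust(pv, method = "BH")
  data.frame(feature_id = table$features$feature_id, fold_change = fc,
             p_value = pv, flag = flag, stringsAsFactors = FALSE)
}
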