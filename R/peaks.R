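#' Construct a detected peak
#'
#' The elementary unit passed between the picking, classification and
#' integration stages: one chromatographic peak from one sample, carrying its
#' apex retention time, boundaries and per-fragment spectrum (apex heights and
#' integrated areas, one entry per m/z channel).
#'
#' @param algorithm character id of the picker that produced the peak.
#' @param sample_id sample identifier.
#' @param rt_apex,rt_start,rt_end apex and boundary retention times (seconds);
#'   must satisfy `rt_start < rt_apex < rt_end`.
#' @param mz numeric vector of fragment m/z values (Th).
#' @param height non-negative apex heights, one per `mz`.
#' @param area non-negative integrated areas, one per `mz`.
#' @param class_label optional quality class, one of `"A"`..`"G"`.
#' @param params_id optional id of the picker parameter set.
#' @param id optional stable peak id.
#' @return an object of class `"gc_peak"`.
#' @export
gc_peak <- function(algorithm, sample_id, rt_apex, rt_start, rt_end,
                    mz, height, area = height,
                    class_label = NA_character_,
                    params_id = NA_character_, id = NA_character_) {
  if (!(rt_start < rt_apex && rt_apex < rt_end)) {
    stopf("invalid peak bounds: need rt_start < rt_apex < rt_end (got %g/%g/%g)",
          rt_start, rt_apex, rt_end)
  }
  if (length(mz) < 1L) stopf("peak must carry at least one m/z channel")
  if (length(height) != length(mz) || length(area) != length(mz)) {
    stopf("mz, height and area must have equal length")
  }
  if (any(height < 0) || any(area < 0)) stopf("heights and areas must be >= 0")
  if (!is.na(class_label) && !class_label %in% CLASS_LEVELS) {
    stopf("unknown class label '%s'", class_label)
  }
  o <- order(mz)
  structure(list(
    algorithm = algorithm, sample_id = sample_id,
    rt_apex = rt_apex, rt_start = rt_start, rt_end = rt_end,
    mz = mz[o], height = height[o], area = area[o],
    class_label = class_label, params_id = params_id, id = id,
    provenance = list(algorithms = unique(algorithm), source_ids = character(0))
  ), class = "gc_peak")
}

#' @export
print.gc_peak <- function(x, ...) {
  cat(sprintf("<gc_peak> %s/%s apex %.2f s [%.2f, %.2f], %d m/z, class %s\n",
              x$algorithm, x$sample_id, x$rt_apex, x$rt_start, x$rt_end,
              length(x$mz), ifelse(is.na(x$class_label), "-", x$class_label)))
  invisible(x)
}

#' Summarise a list of peaks as a data frame
#'
#' @param peaks list of [gc_peak()] objects.
#' @return one row per peak with apex/bounds, channel count, summed apex
#'   height, class label and provenance.
#' @export
peaks_df <- function(peaks) {
  if (!length(peaks)) {
    return(data.frame(algorithm = character(0), sample_id = character(0),
                      rt_apex = numeric(0), rt_start = numeric(0),
                      rt_end = numeric(0), n_mz = integer(0),
                      total_height = numeric(0), class_label = character(0),
                      params_id = character(0), stringsAsFactors = FALSE))
  }
  data.frame(
    algorithm = vapply(peaks, function(p) paste(p$provenance$algorithms, collapse = ";"), ""),
    sample_id = vapply(peaks, `[[`, "", "sample_id"),
    rt_apex = vapply(peaks, `[[`, 0, "rt_apex"),
    rt_start = vapply(peaks, `[[`, 0, "rt_start"),
    rt_end = vapply(peaks, `[[`, 0, "rt_end"),
    n_mz = vapply(peaks, function(p) length(p$mz), 0L),
    total_height = vapply(peaks, function(p) sum(p$height), 0),
    class_label = vapply(peaks, `[[`, "", "class_label"),
    params_id = vapply(peaks, `[[`, "", "params_id"),
    stringsAsFactors = FALSE
  )
}

# Nominal-mass binned cosine similarity between two fragment spectra.
# Used by the duplicate criterion; reverse library matching has its own
# weighted score (see reverse_match).
spectral_cosine <- function(mz1, int1, mz2, int2) {
  b1 <- round(mz1); b2 <- round(mz2)
  u <- sort(unique(c(b1, b2)))
  v1 <- vapply(u, function(m) sum(int1[b1 == m]), 0)
  v2 <- vapply(u, function(m) sum(int2[b2 == m]), 0)
  d <- sqrt(sum(v1^2) * sum(v2^2))
  if (d == 0) return(0)
  sum(v1 * v2) / d
}

peak_cosine <- function(p1, p2) spectral_cosine(p1$mz, p1$height, p2$mz, p2$height)
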