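#' Alkane retention-index calibration
#'
#' @param carbons n-alkane carbon numbers, strictly increasing.
#' @param rts their retention times (s), strictly increasing.
#' @return an object of class `"ri_calibration"`.
#' @export
ri_calibration <- function(carbons, rts) {
  if (length(carbons) != length(rts)) stopf("carbons and rts lengths differ")
  if (length(carbons) < 2L) stopf("need >= 2 alkane anchors")
  if (any(diff(carbons) <= 0) || any(diff(rts) <= 0)) {
    stopf("anchors must be strictly increasing in both coordinates")
  }
  structure(list(carbons = as.double(carbons), rts = as.double(rts)),
            class = "ri_calibration")
}

#' Convert retention time to retention index
#'
#' Linear interpolation between the bracketing alkane anchors:
#' `RI = 100 * (c_n + (rt - rt_n) / (rt_(n+1) - rt_n) * (c_(n+1) - c_n))`,
#' appropriate for temperature-programmed GC. Retention times outside the
#' anchor range are linearly extrapolated from the nearest segment and
#' flagged via the `"extrapolated"` attribute. The classical logarithmic
#' (isothermal Kovats) form is available with `method = "kovats"`.
#'
#' @param cal an [ri_calibration()].
#' @param rt numeric vector of retention times (s).
#' @param method `"linear"` (default) or `"kovats"`.
#' @return retention indices with logical attribute `"extrapolated"`.
#' @export
calibrate_ri <- function(cal, rt, method = c("linear", "kovats")) {
  method <- match.arg(method)
  x <- if (method == "kovats") log(cal$rts) else cal$rts
  q <- if (method == "kovats") log(pmax(rt, min(cal$rts) * 1e-3)) else rt
  n <- length(x)
  seg <- findInterval(q, x, rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1L), n - 1L)
  ri <- 100 * (cal$carbons[seg] +
                 (q - x[seg]) / (x[seg + 1L] - x[seg]) *
                 (cal$carbons[seg + 1L] - cal$carbons[seg]))
  structure(ri, extrapolated = rt < cal$rts[1L] | rt > cal$rts[n])
}

#' Reverse spectral match
#'
#' Weighted cosine computed over the library spectrum's m/z positions only:
#' query fragments absent from the library are ignored, which makes the
#' score robust to co-elution contamination. Both sides are weighted by
#' `mz^mz_power * intensity^int_power` (defaults 2 and 0.5, common for
#' nominal-mass EI spectra). The score is invariant to positive rescaling
#' of either spectrum.
#'
#' @param query_mz,query_int query fragment m/z values and intensities.
#' @param record a [spectrum_record()] (or list with `mz`, `intensity`).
#' @param mz_tol m/z matching tolerance (Th), default 0.5.
#' @param mz_power,int_power weighting exponents.
#' @return similarity in `[0, 1]`.
#' @export
reverse_match <- function(query_mz, query_int, record, mz_tol = 0.5,
                          mz_power = 2, int_power = 0.5) {
  if (!length(record$mz)) stopf("empty library spectrum")
  if (!length(query_mz)) stopf("empty query spectrum")
  qi <- vapply(record$mz, function(m) {
    sel <- abs(query_mz - m) <= mz_tol
    if (any(sel)) max(query_int[sel]) else 0
  }, 0)
  uq <- record$mz^mz_power * qi^int_power
  ul <- record$mz^mz_power * record$intensity^int_power
  d <- sqrt(sum(uq^2) * sum(ul^2))
  if (d == 0) return(0)
  min(1, sum(uq * ul) / d)
}

#' Annotation configuration
#'
#' The two-tier confidence rule: a candidate must fall within `ri_window`
#' retention-index units; it is reported with high confidence only when its
#' similarity additionally exceeds `min_similarity`, and with low confidence
#' otherwise.
#'
#' @param ri_window RI gate (default 1.5 RI units).
#' @param min_similarity high-confidence similarity gate (default 0.9).
#' @param mz_tol m/z matching tolerance (Th) for [reverse_match()].
#' @return an object of class `"annotation_config"`.
#' @export
annotation_config <- function(ri_window = 1.5, min_similarity = 0.9,
                              mz_tol = 0.5) {
  if (ri_window <= 0) stopf("ri_window must be > 0")
  if (min_similarity <= 0 || min_similarity > 1) {
    stopf("min_similarity must lie in (0, 1]")
  }
  structure(list(ri_window = ri_window, min_similarity = min_similarity,
                 mz_tol = mz_tol), class = "annotation_config")
}

#' Annotate features against a spectral library
#'
#' For every feature, library entries within the RI window are candidates;
#' the best candidate by reverse-match similarity is reported. Confidence is
#' `"high"` iff the similarity exceeds the gate, `"low"` otherwise.
#' Features with no candidate in the window get no hit.
#'
#' @param x a `final_peak_set` (high partition), `feature_table`, or list of
#'   [gc_peak()].
#' @param library list of [spectrum_record()] carrying retention indices.
#' @param cal an [ri_calibration()] used to compute feature RIs from RTs.
#' @param cfg an [annotation_config()].
#' @return data frame: `feature_id, compound, similarity, delta_ri,
#'   confidence`.
#' @export
annotate_features <- function(x, library, cal, cfg = annotation_config()) {
  feats <- as_feature_list(x)
  lib_ri <- vapply(library, function(r) as.double(r$ri %||% NA_real_), 0)
  if (anyNA(lib_ri)) stopf("library records must carry retention indices")
  hits <- list()
  for (f in feats) {
    ri <- as.double(calibrate_ri(cal, f$rt_apex))
    dri <- ri - lib_ri
    cand <- which(abs(dri) <= cfg$ri_window)
    if (!length(cand)) next
    sims <- vapply(cand, function(j) {
      reverse_match(f$mz, f$height, library[[j]], mz_tol = cfg$mz_tol)
    }, 0)
    b <- which.max(sims)
    hits[[length(hits) + 1L]] <- data.frame(
      feature_id = f$id, compound = library[[cand[b]]]$name,
      similarity = sims[b], delta_ri = dri[cand[b]],
      confidence = if (sims[b] > cfg$min_similarity) "high" else "low",
      stringsAsFactors = FALSE)
  }
  if (!length(hits)) {
    return(data.frame(feature_id = character(0), compound = character(0),
                      similarity = numeric(0), delta_ri = numeric(0),
                      confidence = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

#' Build a spectral library from compound specifications
#'
#' Convenience for self-annotation of simulated runs: each simulated
#' compound becomes a library record with its fragment abundances and the
#' retention index of its apex under the given calibration.
#'
#' @param compounds list of [compound_spec()].
#' @param cal an [ri_calibration()].
#' @return list of [spectrum_record()].
#' @export
library_from_compounds <- function(compounds, cal) {
  lapply(compounds, function(cp) {
    spectrum_record(cp$name, cbind(cp$mz, cp$abundance),
                    ri = as.double(calibrate_ri(cal, cp$rt_apex)))
  })
}
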