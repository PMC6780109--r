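# Pluggable peak pickers. A picker is any function with signature
# (raw_run, picker_params) -> list of gc_peak, registered together with a
# grid schema declaring its parameter names and legal ranges.

picker_registry <- new.env(parent = emptyenv())

#' Register a peak-picking algorithm
#'
#' @param name algorithm id.
#' @param fun function `(run, params) -> list of gc_peak`.
#' @param schema named list of length-2 numeric ranges, one per parameter.
#' @return `name`, invisibly.
#' @export
register_picker <- function(name, fun, schema) {
  stopifnot(is.function(fun), is.list(schema), length(names(schema)) == length(schema))
  assign(name, list(fun = fun, schema = schema), envir = picker_registry)
  invisible(name)
}

#' List registered picker algorithm ids
#' @return character vector.
#' @export
list_pickers <- function() sort(ls(picker_registry))

#' Grid schema of a registered picker
#' @param name algorithm id.
#' @return named list of parameter ranges.
#' @export
picker_grid_schema <- function(name) get_picker(name)$schema

get_picker <- function(name) {
  if (!exists(name, envir = picker_registry)) {
    stopf("unknown picker '%s' (registered: %s)", name,
          paste(list_pickers(), collapse = ", "))
  }
  get(name, envir = picker_registry)
}

#' Construct a validated picker parameter set
#'
#' @param algorithm registered picker id.
#' @param values named list of parameter values; names and ranges are checked
#'   against the algorithm's grid schema.
#' @param grid_id optional identifier of the grid point.
#' @return an object of class `"picker_params"`.
#' @export
picker_params <- function(algorithm, values, grid_id = NA_character_) {
  schema <- picker_grid_schema(algorithm)
  unknown <- setdiff(names(values), names(schema))
  if (length(unknown)) {
    stopf("picker '%s': unknown parameter(s) %s", algorithm,
          paste(unknown, collapse = ", "))
  }
  missing <- setdiff(names(schema), names(values))
  if (length(missing)) {
    stopf("picker '%s': missing parameter(s) %s", algorithm,
          paste(missing, collapse = ", "))
  }
  for (nm in names(values)) {
    r <- schema[[nm]]
    if (values[[nm]] < r[1] || values[[nm]] > r[2]) {
      stopf("picker '%s': %s = %g outside declared range [%g, %g]",
            algorithm, nm, values[[nm]], r[1], r[2])
    }
  }
  if (is.na(grid_id)) {
    grid_id <- paste0(algorithm, ":",
                      paste(sprintf("%s=%g", names(values),
                                    unlist(values)), collapse = ","))
  }
  structure(list(algorithm = algorithm, values = values, grid_id = grid_id),
            class = "picker_params")
}

#' Run a registered picker
#'
#' @param run a [raw_run()].
#' @param params a [picker_params()].
#' @return list of [gc_peak()].
#' @export
run_picker <- function(run, params) {
  get_picker(params$algorithm)$fun(run, params)
}

# robust noise scale of a filter response
mad_sd <- function(x) 1.4826 * stats::mad(x, center = stats::median(x), constant = 1)

# second-derivative-of-Gaussian (Mexican hat) kernel, L2-normalised
ricker_kernel <- function(sigma_pts) {
  half <- max(3L, ceiling(4 * sigma_pts))
  x <- (-half):half
  k <- (1 - (x / sigma_pts)^2) * exp(-0.5 * (x / sigma_pts)^2)
  k <- k - mean(k)            # zero mean: flat baselines give zero response
  k / sqrt(sum(k^2))
}

# centred convolution with edge replication (zero padding would fabricate
# response spikes at the ends of runs with elevated baselines, e.g. bleed)
conv_same <- function(x, k) {
  half <- (length(k) - 1L) %/% 2L
  n <- length(x)
  y <- stats::filter(c(rep(x[1L], half), x, rep(x[n], half)), rev(k), sides = 2)
  as.double(y[(half + 1L):(half + n)])
}

# walk from apex to the nearest non-positive response on each side
response_bounds <- function(resp, apex) {
  n <- length(resp)
  li <- apex
  while (li > 1L && resp[li - 1L] > 0) li <- li - 1L
  ri <- apex
  while (ri < n && resp[ri + 1L] > 0) ri <- ri + 1L
  c(max(1L, li - 1L), min(n, ri + 1L))
}

# shared per-EIC peak assembly
eic_peaks <- function(eic, apexes, bounds, algorithm, sample_id, params) {
  dt <- stats::median(diff(eic$rt))
  lapply(seq_along(apexes), function(j) {
    a <- apexes[j]; b <- bounds[[j]]
    sel <- b[1]:b[2]
    # peaks at the run border: keep bounds strictly bracketing the apex
    rt_start <- if (b[1] < a) eic$rt[b[1]] else eic$rt[a] - dt / 2
    rt_end <- if (b[2] > a) eic$rt[b[2]] else eic$rt[a] + dt / 2
    gc_peak(algorithm = algorithm, sample_id = sample_id,
            rt_apex = eic$rt[a], rt_start = rt_start, rt_end = rt_end,
            mz = eic$mz_center, height = eic$intensity[a],
            area = trapz(eic$rt[sel], eic$intensity[sel]),
            params_id = params$grid_id)
  })
}

#' Matched-filter peak picker
#'
#' Convolves every EIC with a Gaussian second-derivative kernel of the stated
#' FWHM; local maxima of the response above `snthresh` times a robust noise
#' estimate (1.4826 x MAD of the response) are reported as peaks, with
#' boundaries at the nearest zero-crossings of the response. Parameters:
#' `fwhm` (s), `snthresh`, `step` (EIC bin width, Th), `max_per_eic`.
#'
#' @param run a [raw_run()].
#' @param params [picker_params()] for algorithm `"matched_filter"`.
#' @return list of single-m/z [gc_peak()]; group with [group_pseudospectra()].
#' @export
pick_matched_filter <- function(run, params) {
  v <- params$values
  rts <- run_rts(run)
  dt <- stats::median(diff(rts))
  if (v$fwhm < 2 * dt) stopf("fwhm below sampling resolution (%.3g s < 2 x %.3g s)",
                             v$fwhm, dt)
  sigma_pts <- v$fwhm / 2.3548 / dt
  k <- ricker_kernel(sigma_pts)
  eics <- bin_to_eics(run, v$step)
  out <- list()
  for (eic in eics) {
    resp <- conv_same(eic$intensity, k)
    sd_n <- mad_sd(resp)
    thr <- v$snthresh * max(sd_n, 1e-9 * max(abs(resp), 1e-300))
    apexes <- local_maxima(resp)
    apexes <- apexes[resp[apexes] > thr]
    if (!length(apexes)) next
    if (length(apexes) > v$max_per_eic) {
      apexes <- apexes[order(resp[apexes], decreasing = TRUE)[seq_len(v$max_per_eic)]]
      apexes <- sort(apexes)
    }
    bounds <- lapply(apexes, function(a) response_bounds(resp, a))
    # snap apex to the EIC intensity maximum inside the bounds
    apexes <- vapply(seq_along(apexes), function(j) {
      sel <- bounds[[j]][1]:bounds[[j]][2]
      sel[which.max(eic$intensity[sel])]
    }, 0L)
    out <- c(out, eic_peaks(eic, apexes, bounds, "matched_filter",
                            run$sample_id, params))
  }
  out
}

#' CWT peak picker
#'
#' Mexican-hat continuous wavelet transform over scales spanning
#' `[peakwidth_min, peakwidth_max]` (s). EICs failing the prefilter (fewer
#' than `prefilter_k` consecutive points above `prefilter_i` counts) are
#' skipped. Candidate apexes are local maxima of the best-scale response
#' above `snthresh` times a robust noise estimate; the reported width comes
#' from the best-matching scale and the measured full width at half maximum
#' must fall within `[0.5 * peakwidth_min, 2 * peakwidth_max]` (scale-mismatch
#' gate). Boundaries are apex +/- 1.5 x scale, clipped to the run.
#'
#' @param run a [raw_run()].
#' @param params [picker_params()] for algorithm `"cwt"`.
#' @return list of single-m/z [gc_peak()]; group with [group_pseudospectra()].
#' @export
pick_cwt <- function(run, params) {
  v <- params$values
  if (v$peakwidth_min >= v$peakwidth_max) {
    stopf("peakwidth_min must be < peakwidth_max")
  }
  rts <- run_rts(run)
  dt <- stats::median(diff(rts))
  widths <- unique(seq(v$peakwidth_min, v$peakwidth_max, length.out = 6))
  sigmas_pts <- pmax(widths / 2.3548 / dt, 0.7)
  eics <- bin_to_eics(run, 1)
  out <- list()
  for (eic in eics) {
    x <- eic$intensity
    r <- rle(x >= v$prefilter_i)
    if (!any(r$values & r$lengths >= v$prefilter_k)) next
    resp <- vapply(sigmas_pts, function(s) conv_same(x, ricker_kernel(s)),
                   numeric(length(x)))
    best <- apply(resp, 1L, max)
    best_scale <- apply(resp, 1L, which.max)
    sd_n <- mad_sd(resp[, 1L])
    thr <- v$snthresh * max(sd_n, 1e-9 * max(abs(best), 1e-300))
    apexes <- local_maxima(best)
    apexes <- apexes[best[apexes] > thr]
    if (!length(apexes)) next
    keep <- logical(length(apexes))
    scales_s <- numeric(length(apexes))
    for (j in seq_along(apexes)) {
      a <- apexes[j]
      s_idx <- best_scale[a]
      scales_s[j] <- widths[s_idx] / 2
      # measured FWHM around the apex on the raw trace
      half <- x[a] / 2
      li <- a; while (li > 1L && x[li - 1L] > half) li <- li - 1L
      ri <- a; while (ri < length(x) && x[ri + 1L] > half) ri <- ri + 1L
      fw <- (ri - li) * dt
      keep[j] <- fw >= 0.5 * v$peakwidth_min && fw <= 2 * v$peakwidth_max
    }
    apexes <- apexes[keep]; scales_s <- scales_s[keep]
    if (!length(apexes)) next
    if (length(apexes) > v$max_per_eic) {
      o <- order(best[apexes], decreasing = TRUE)[seq_len(v$max_per_eic)]
      apexes <- apexes[sort(o)]; scales_s <- scales_s[sort(o)]
    }
    bounds <- lapply(seq_along(apexes), function(j) {
      c(max(1L, a_idx(rts, rts[apexes[j]] - 1.5 * scales_s[j])),
        min(length(x), a_idx(rts, rts[apexes[j]] + 1.5 * scales_s[j])))
    })
    # snap apex to the intensity maximum inside the bounds
    apexes <- vapply(seq_along(apexes), function(j) {
      sel <- bounds[[j]][1]:bounds[[j]][2]
      sel[which.max(x[sel])]
    }, 0L)
    ok <- vapply(seq_along(apexes), function(j) {
      bounds[[j]][1] < apexes[j] && apexes[j] < bounds[[j]][2]
    }, TRUE)
    out <- c(out, eic_peaks(eic, apexes[ok], bounds[ok], "cwt",
                            run$sample_id, params))
  }
  out
}

a_idx <- function(rts, t) which.min(abs(rts - t))

#' Group single-m/z hits into pseudospectra
#'
#' Co-eluting single-channel peaks from one sample and one algorithm whose
#' apexes lie within `rt_tol` (single linkage) are merged into one compound-
#' level peak: the m/z list is the union, the apex RT the height-weighted
#' mean, and the bounds the envelope union. This stage stands in for a
#' dedicated spectral deconvolution step.
#'
#' @param peaks list of [gc_peak()] from one sample and one algorithm.
#' @param rt_tol apex tolerance (s).
#' @return list of grouped [gc_peak()].
#' @export
group_pseudospectra <- function(peaks, rt_tol = 1) {
  if (length(peaks) <= 1L) return(peaks)
  alg <- unique(vapply(peaks, `[[`, "", "algorithm"))
  smp <- unique(vapply(peaks, `[[`, "", "sample_id"))
  if (length(alg) > 1L || length(smp) > 1L) {
    stopf("group_pseudospectra expects peaks from one sample and one algorithm")
  }
  apex <- vapply(peaks, `[[`, 0, "rt_apex")
  o <- order(apex)
  grp <- cumsum(c(1L, as.integer(diff(apex[o]) > rt_tol)))
  lapply(split(o, grp), function(idx) {
    members <- peaks[idx]
    if (length(members) == 1L) return(members[[1L]])
    mz <- unlist(lapply(members, `[[`, "mz"))
    h <- unlist(lapply(members, `[[`, "height"))
    ar <- unlist(lapply(members, `[[`, "area"))
    # one entry per m/z: keep the strongest if channels collide
    ok <- order(h, decreasing = TRUE)
    first <- !duplicated(mz[ok])
    sel <- ok[first]
    wts <- vapply(members, function(p) max(p$height), 0)
    gc_peak(algorithm = alg, sample_id = smp,
            rt_apex = sum(vapply(members, `[[`, 0, "rt_apex") * wts) / sum(wts),
            rt_start = min(vapply(members, `[[`, 0, "rt_start")),
            rt_end = max(vapply(members, `[[`, 0, "rt_end")),
            mz = mz[sel], height = h[sel], area = ar[sel],
            params_id = members[[1L]]$params_id)
  })
}

# register built-ins on load
register_builtin_pickers <- function() {
  register_picker("matched_filter", pick_matched_filter,
                  schema = list(fwhm = c(0.2, 60), snthresh = c(0, 1e6),
                                step = c(0.01, 10), max_per_eic = c(1, 1000)))
  register_picker("cwt", pick_cwt,
                  schema = list(peakwidth_min = c(0.2, 120),
                                peakwidth_max = c(0.3, 240),
                                snthresh = c(0, 1e6),
                                prefilter_k = c(1, 100),
                                prefilter_i = c(0, 1e9),
                                max_per_eic = c(1, 1000)))
}

.onLoad <- function(libname, pkgname) {
  register_builtin_pickers()
}
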