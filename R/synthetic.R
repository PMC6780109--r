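#' Specify a simulated compound
#'
#' A compound elutes as a Gaussian or exponentially modified Gaussian (EMG)
#' profile shared across its electron-ionisation fragments. Defaults emulate
#' temperature-programmed capillary GC where full peak base widths are
#' around 4 s.
#'
#' @param name compound name.
#' @param rt_apex apex retention time (s).
#' @param fragments two-column matrix/data frame of (mz, relative abundance
#'   in (0, 1]); at least one abundance must equal 1.
#' @param max_intensity apex height of the base fragment (counts).
#' @param fwhm full width at half maximum (s); the default 1.7 s gives a
#'   full base width of about 4 s.
#' @param shape `"gaussian"` or `"emg"`.
#' @param emg_tau exponential tail constant (s, >= 0) for `"emg"`.
#' @return an object of class `"compound_spec"`.
#' @export
compound_spec <- function(name, rt_apex, fragments, max_intensity = 1e5,
                          fwhm = 1.7, shape = c("gaussian", "emg"),
                          emg_tau = 0) {
  shape <- match.arg(shape)
  fragments <- as.matrix(fragments)
  if (nrow(fragments) < 1L) stopf("compound '%s': needs >= 1 fragment", name)
  ab <- fragments[, 2L]
  if (any(ab <= 0) || any(ab > 1)) {
    stopf("compound '%s': relative abundances must lie in (0, 1]", name)
  }
  if (max(ab) < 1) stopf("compound '%s': one abundance must equal 1", name)
  if (emg_tau < 0) stopf("compound '%s': emg_tau must be >= 0", name)
  structure(list(name = name, rt_apex = rt_apex,
                 mz = as.double(fragments[, 1L]), abundance = as.double(ab),
                 max_intensity = max_intensity, fwhm = fwhm,
                 shape = shape, emg_tau = emg_tau),
            class = "compound_spec")
}

#' Specify the chromatographic noise model
#'
#' Covers a flat electronic baseline with slow linear drift, end-of-run
#' column bleed (monotonically rising baseline after `bleed_onset`),
#' Gaussian shot noise truncated at zero, and sporadic one-scan spikes.
#'
#' @param baseline_level flat baseline (counts).
#' @param baseline_drift_slope linear drift (counts/s).
#' @param bleed_onset column-bleed onset (s).
#' @param bleed_slope bleed ramp (counts/s).
#' @param shot_noise_sd shot-noise standard deviation (counts).
#' @param spike_rate spike events per minute.
#' @return an object of class `"noise_model"`.
#' @export
noise_model <- function(baseline_level = 30, baseline_drift_slope = 0.02,
                        bleed_onset = 250, bleed_slope = 2,
                        shot_noise_sd = 10, spike_rate = 0.5) {
  v <- c(baseline_level, baseline_drift_slope, bleed_onset, bleed_slope,
         shot_noise_sd, spike_rate)
  if (any(v < 0)) stopf("all noise model parameters must be non-negative")
  structure(list(baseline_level = baseline_level,
                 baseline_drift_slope = baseline_drift_slope,
                 bleed_onset = bleed_onset, bleed_slope = bleed_slope,
                 shot_noise_sd = shot_noise_sd, spike_rate = spike_rate),
            class = "noise_model")
}

# elution profile on a time grid, normalised to apex 1
elution_profile <- function(t, rt_apex, fwhm, shape = "gaussian", tau = 0) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  if (shape == "gaussian" || tau <= 1e-9) {
    return(exp(-0.5 * ((t - rt_apex) / sigma)^2))
  }
  z <- sigma / tau - (t - rt_apex) / sigma
  h <- exp(0.5 * (sigma / tau)^2 - (t - rt_apex) / tau) * erfc(z / sqrt(2))
  m <- max(h)
  if (m <= 0 || !is.finite(m)) return(exp(-0.5 * ((t - rt_apex) / sigma)^2))
  h / m
}

#' Simulate a GC-MS run with ground truth
#'
#' Each compound contributes its elution profile on all of its fragment m/z
#' channels; the noise model adds baseline, drift, bleed, truncated Gaussian
#' shot noise and spikes on every channel (fragment channels plus
#' `noise_channels`). Deterministic given `seed`.
#'
#' @param compounds list of [compound_spec()].
#' @param noise a [noise_model()].
#' @param rt_range length-2 numeric, run start/end (s).
#' @param scan_hz scan rate (Hz); default 5.
#' @param seed integer seed.
#' @param sample_id sample id of the returned run.
#' @param noise_channels m/z channels carrying only noise (and bleed).
#' @param rt_shift per-sample RT offset (s) applied to every compound.
#' @return list with `run` (a [raw_run()]) and `truth` (data frame:
#'   compound, mz, rt_apex_s, rt_start_s, rt_end_s, class).
#' @export
simulate_run <- function(compounds, noise = noise_model(),
                         rt_range = c(0, 300), scan_hz = 5, seed = 1,
                         sample_id = "sim", noise_channels = default_noise_channels(),
                         rt_shift = 0) {
  if (diff(rt_range) <= 0) stopf("rt_range must have positive length")
  if (scan_hz <= 0) stopf("scan_hz must be > 0")
  for (cp in compounds) {
    a <- cp$rt_apex + rt_shift
    if (a < rt_range[1] || a > rt_range[2]) {
      stopf("compound '%s': rt_apex %.1f s outside rt_range [%g, %g]",
            cp$name, a, rt_range[1], rt_range[2])
    }
  }
  t <- seq(rt_range[1], rt_range[2], by = 1 / scan_hz)
  nt <- length(t)
  channels <- sort(unique(c(unlist(lapply(compounds, `[[`, "mz")), noise_channels)))
  nch <- length(channels)
  sig <- matrix(0, nrow = nch, ncol = nt)
  truth <- vector("list", length(compounds))
  half_base <- function(cp) 2.47 * cp$fwhm / 2.3548  # half the width at 5% height
  for (k in seq_along(compounds)) {
    cp <- compounds[[k]]
    apex <- cp$rt_apex + rt_shift
    prof <- elution_profile(t, apex, cp$fwhm, cp$shape, cp$emg_tau)
    rows <- match(cp$mz, channels)
    sig[rows, ] <- sig[rows, ] +
      outer(cp$abundance * cp$max_intensity, prof)
    hb <- half_base(cp)
    # the observable apex: for skewed (EMG) profiles the mode, not the
    # Gaussian centre; evaluated on a fine grid
    tf <- seq(max(rt_range[1], apex - 3 * cp$fwhm),
              min(rt_range[2], apex + 3 * cp$fwhm + 4 * cp$emg_tau),
              length.out = 800)
    apex_obs <- tf[which.max(elution_profile(tf, apex, cp$fwhm, cp$shape,
                                             cp$emg_tau))]
    truth[[k]] <- data.frame(compound = cp$name, mz = cp$mz,
                             rt_apex_s = apex_obs, rt_start_s = apex_obs - hb,
                             rt_end_s = apex_obs + hb, class = "B",
                             stringsAsFactors = FALSE)
  }
  base <- noise$baseline_level + noise$baseline_drift_slope * (t - t[1]) +
    ifelse(t > noise$bleed_onset, noise$bleed_slope * (t - noise$bleed_onset), 0)
  with_seed(seed, {
    mat <- sig + rep(base, each = nch)
    if (noise$shot_noise_sd > 0) {
      mat <- mat + matrix(stats::rnorm(nch * nt, 0, noise$shot_noise_sd), nch, nt)
    }
    if (noise$spike_rate > 0) {
      nspk <- stats::rpois(1, noise$spike_rate * diff(rt_range) / 60)
      if (nspk > 0) {
        si <- sample.int(nt, nspk, replace = TRUE)
        sj <- sample.int(nch, nspk, replace = TRUE)
        amp <- stats::rlnorm(nspk, log(20 * (noise$baseline_level + 1)), 0.5)
        for (q in seq_len(nspk)) mat[sj[q], si[q]] <- mat[sj[q], si[q]] + amp[q]
      }
    }
    mat[mat < 0] <- 0
    scans <- lapply(seq_len(nt), function(i) {
      list(rt = t[i], mz = channels, intensity = mat[, i])
    })
    list(run = raw_run(scans, sample_id = sample_id, source_path = ""),
         truth = do.call(rbind, truth) %||%
           data.frame(compound = character(0), mz = numeric(0),
                      rt_apex_s = numeric(0), rt_start_s = numeric(0),
                      rt_end_s = numeric(0), class = character(0)))
  })
}

#' @rdname simulate_run
#' @export
default_noise_channels <- function() c(59.2, 85.4, 111.7, 133.3, 159.8, 191.1, 223.6, 262.9)

#' Draw a random compound panel
#'
#' Apexes are spaced at least `min_sep` apart inside `rt_range` (shrunk by a
#' margin); each compound gets 4-8 fragments from a nominal EI m/z pool with
#' a base fragment at abundance 1, and a log-uniform apex intensity.
#'
#' @param n number of compounds.
#' @param rt_range run RT range (s).
#' @param seed integer seed.
#' @param min_sep minimal apex separation (s).
#' @param intensity_range log-uniform range of apex heights (counts).
#' @return list of [compound_spec()].
#' @export
random_compound_set <- function(n, rt_range = c(0, 300), seed = 1,
                                min_sep = 8, intensity_range = c(2e4, 1e6)) {
  with_seed(seed, {
    lo <- rt_range[1] + 15; hi <- rt_range[2] - 15
    slots <- seq(lo, hi, by = min_sep)
    if (length(slots) < n) {
      stopf("rt_range too short for %d compounds at min_sep %g", n, min_sep)
    }
    apex <- sort(sample(slots, n)) + stats::runif(n, -min_sep / 4, min_sep / 4)
    pool <- c(55, 57, 60, 66, 70, 73, 75, 82, 91, 100, 103, 117, 129, 142,
              147, 156, 174, 188, 205, 217, 229, 246, 258, 273, 281, 299)
    lapply(seq_len(n), function(i) {
      nf <- sample(4:8, 1)
      mz <- sort(sample(pool, nf)) + round(stats::runif(nf, -0.2, 0.2), 3)
      ab <- c(1, sort(stats::runif(nf - 1, 0.08, 0.85), decreasing = TRUE))
      compound_spec(sprintf("cmpd_%02d", i), apex[i], cbind(mz, ab),
                    max_intensity = exp(stats::runif(1, log(intensity_range[1]),
                                                     log(intensity_range[2]))),
                    fwhm = stats::runif(1, 1.4, 2.0),
                    shape = if (stats::runif(1) < 0.3) "emg" else "gaussian",
                    emg_tau = stats::runif(1, 0.1, 0.5))
    })
  })
}

# ---- class-window templates -------------------------------------------------

gaussian_trace <- function(n_t, apex, sigma) {
  exp(-0.5 * ((seq_len(n_t) - apex) / sigma)^2)
}

# separation between two unit-width Gaussians giving a target valley-to-apex
# ratio (ratio measured against the smaller apex of the summed trace)
solve_g_separation <- function(sigma, amp2, target) {
  ratio_at <- function(d) {
    x <- seq(-4 * sigma, d + 4 * sigma, length.out = 400)
    s <- exp(-0.5 * (x / sigma)^2) + amp2 * exp(-0.5 * ((x - d) / sigma)^2)
    pk <- range(s[c(which.min(abs(x)), which.min(abs(x - d)))])
    mid <- s[x > 0.15 * d & x < 0.85 * d]
    if (!length(mid)) return(1)
    min(mid) / pk[1]
  }
  f <- function(d) ratio_at(d) - target
  lo <- 1.4 * sigma; hi <- 6 * sigma
  if (f(lo) < 0) return(lo)
  if (f(hi) > 0) return(hi)
  stats::uniroot(f, c(lo, hi), tol = 1e-3)$root
}

#' Generate a labelled peak window of a given class
#'
#' Produces an apex-centred m/z-by-time intensity window following one of the
#' seven class templates: (A) apex shifted left, (B) centred apex, (C) apex
#' shifted right, (D) noise only, (E) narrow peak with wide margins, (F) peak
#' truncated by a window border, (G) merged/shoulder doublet with a valley.
#' Channel noise is scaled so that apex / noise-sd equals `snr`.
#'
#' @param label class label, one of `"A"`..`"G"`.
#' @param n_mz number of m/z channels (>= 3).
#' @param n_t number of time points (>= 9).
#' @param snr apex signal-to-noise ratio.
#' @param seed integer seed.
#' @param window_s window span in seconds; must match the span used when
#'   extracting windows around detected peaks so that template and real
#'   peak geometries agree.
#' @return a `peak_window` (list with `intensities` `n_mz x n_t` matrix,
#'   `mz_centers`, `rt_grid`) with attribute `"label"`.
#' @export
generate_class_window <- function(label, n_mz = 10, n_t = 41, snr = 50,
                                  seed = 1, window_s = 8) {
  if (!label %in% CLASS_LEVELS) stopf("unknown class label '%s'", label)
  if (n_mz < 3L) stopf("n_mz must be >= 3")
  if (n_t < 9L) stopf("n_t must be >= 9")
  with_seed(seed, {
    centre <- (n_t + 1) / 2
    # compound spectra carry a variable number of fragments; windows around
    # detected peaks are zero-padded to n_mz channels, so templates emulate
    # the same layout: n_active populated channels, the rest exactly zero
    n_active <- sample(max(3L, min(4L, n_mz)):n_mz, 1)
    amp_ch <- c(1, sort(stats::runif(n_active - 1, 0.1, 0.9), decreasing = TRUE),
                rep(0, n_mz - n_active))
    A <- 1000
    # sigma spans the widths implied by ~3.5-5 s full base widths seen
    # through the default 8 s / 41-point window
    sigma_std <- stats::runif(1, 0.072, 0.104) * n_t
    base <- matrix(0, n_mz, n_t)
    if (label %in% c("A", "B", "C")) {
      shift <- switch(label,
        A = -stats::runif(1, 0.25, 0.32) * n_t,
        B = stats::runif(1, -0.05, 0.05) * n_t,
        C = stats::runif(1, 0.25, 0.32) * n_t)
      tr <- gaussian_trace(n_t, centre + shift, sigma_std)
      base <- outer(amp_ch, tr) * A
    } else if (label == "E") {
      sigma <- stats::runif(1, 0.028, 0.040) * n_t
      tr <- gaussian_trace(n_t, centre + stats::runif(1, -0.04, 0.04) * n_t, sigma)
      base <- outer(amp_ch, tr) * A
    } else if (label == "F") {
      d <- stats::runif(1, 0.02, 0.09) * n_t
      apex <- if (stats::runif(1) < 0.5) d else n_t + 1 - d
      tr <- gaussian_trace(n_t, apex, sigma_std)
      base <- outer(amp_ch, tr) * A
    } else if (label == "G") {
      amp2 <- stats::runif(1, 0.75, 0.95)
      valley <- stats::runif(1, 0.55, 0.90)
      sep <- solve_g_separation(sigma_std, amp2, valley)
      a1 <- centre - sep / 2
      tr <- gaussian_trace(n_t, a1, sigma_std) +
        amp2 * gaussian_trace(n_t, a1 + sep, sigma_std)
      base <- outer(amp_ch, tr) * A
    }
    sd_n <- A / snr
    noise <- matrix(0, n_mz, n_t)
    noise[seq_len(n_active), ] <- stats::rnorm(n_active * n_t, 0, sd_n)
    offs <- c(stats::runif(n_active, 0, 0.05 * A), rep(0, n_mz - n_active))
    m <- base + noise + offs
    m[m < 0] <- 0
    w <- peak_window(m, mz_centers = 50 + 10 * seq_len(n_mz),
                     rt_grid = seq(0, window_s, length.out = n_t))
    attr(w, "label") <- label
    w
  })
}

#' Rule-based template checker
#'
#' Re-derives a class label from window geometry alone (summed smoothed
#' trace: presence, local-maxima count and valley depth, border truncation,
#' width fraction, apex position). Used to verify that the seven templates
#' are mutually separable and to auto-label synthetic training windows.
#'
#' @param window a `peak_window`.
#' @return a single class label `"A"`..`"G"`.
#' @export
check_window_class <- function(window) {
  s <- colSums(window$intensities)
  n <- length(s)
  sm <- smooth3(s)
  sm <- sm - min(sm)                      # flat baseline removal
  # noise from the high-frequency residual (slope-insensitive)
  sd_n <- 1.4826 * stats::mad(s - smooth3(s)) / sqrt(2 / 3)
  if (max(sm) < 10 * max(sd_n, 1e-12)) return("D")
  mx <- max(sm)
  cand <- local_maxima(sm)
  cand <- cand[sm[cand] > 0.3 * mx]
  # merge candidate maxima closer than 3 points, keep the higher
  if (length(cand) > 1L) {
    keep <- c()
    for (i in cand) {
      if (length(keep) && i - keep[length(keep)] < 3L) {
        if (sm[i] > sm[keep[length(keep)]]) keep[length(keep)] <- i
      } else keep <- c(keep, i)
    }
    cand <- keep
  }
  if (length(cand) >= 2L) {
    o <- cand[order(sm[cand], decreasing = TRUE)][1:2]
    o <- sort(o)
    valley <- min(sm[o[1]:o[2]])
    if (valley <= 0.95 * min(sm[o])) return("G")
  }
  if (max(sm[c(1L, 2L, n - 1L, n)]) > 0.45 * mx) return("F")
  above <- which(sm >= 0.1 * mx)
  if ((max(above) - min(above) + 1L) < 0.30 * n) return("E")
  rel <- (which.max(sm) - (n + 1) / 2) / n
  if (rel <= -0.15) return("A")
  if (rel >= 0.15) return("C")
  "B"
}

#' Generate a balanced labelled training corpus
#'
#' @param n_per_class windows per class; the default 100 yields 700 windows,
#'   matching the recommended minimum training-set size.
#' @param seed integer seed.
#' @param snr apex signal-to-noise ratio of every window.
#' @param n_mz,n_t window dimensions.
#' @return list with `windows` (list of `peak_window`) and `labels`
#'   (character vector); each window carries a stable `"window_id"` attribute.
#' @export
generate_training_corpus <- function(n_per_class = 100, seed = 1, snr = 50,
                                     n_mz = 10, n_t = 41, window_s = 8) {
  if (n_per_class < 1L) stopf("n_per_class must be >= 1")
  labels <- rep(CLASS_LEVELS, each = n_per_class)
  windows <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    w <- generate_class_window(labels[i], n_mz = n_mz, n_t = n_t, snr = snr,
                               seed = derive_seed(seed, i), window_s = window_s)
    attr(w, "window_id") <- sprintf("corpus%d_w%04d_%s", seed, i, labels[i])
    windows[[i]] <- w
  }
  list(windows = windows, labels = labels)
}
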