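#' Bin a run into extracted ion chromatograms
#'
#' Every (m/z, intensity) point of every scan contributes to exactly one bin
#' of width `bin_width` (bin k covers `[k*bin_width, (k+1)*bin_width)`).
#' Per-bin traces are sampled on the run's scan grid with zeros where a scan
#' has no point in the bin; empty bins are dropped.
#'
#' @param run a [raw_run()].
#' @param bin_width bin width (Th), > 0.
#' @return list of EICs, each a list with `mz_center`, `rt`, `intensity`.
#' @export
bin_to_eics <- function(run, bin_width = 1) {
  if (bin_width <= 0) stopf("bin_width must be > 0")
  rts <- run_rts(run)
  nt <- length(rts)
  scan_idx <- rep.int(seq_len(nt),
                      vapply(run$scans, function(s) length(s$mz), 0L))
  mz <- unlist(lapply(run$scans, `[[`, "mz"), use.names = FALSE)
  int <- unlist(lapply(run$scans, `[[`, "intensity"), use.names = FALSE)
  if (!length(mz)) return(list())
  bin <- floor(mz / bin_width)
  ubins <- sort(unique(bin))
  lapply(ubins, function(b) {
    sel <- bin == b
    y <- numeric(nt)
    # accumulate: several points of one scan may fall in the same bin
    acc <- tapply(int[sel], scan_idx[sel], sum)
    y[as.integer(names(acc))] <- as.double(acc)
    list(mz_center = (b + 0.5) * bin_width, rt = rts, intensity = y)
  })
}

# trace for one target m/z channel (+/- tol), on the run's scan grid
extract_eic <- function(run, mz_target, tol = 0.5) {
  vapply(run$scans, function(s) {
    sel <- abs(s$mz - mz_target) <= tol
    if (any(sel)) sum(s$intensity[sel]) else 0
  }, 0)
}
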