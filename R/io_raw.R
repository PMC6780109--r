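#' Construct a raw GC-MS run
#'
#' A run is an RT-ordered list of centroided scans. Each scan is a list with
#' `rt` (seconds), `mz` (strictly ascending, Th) and `intensity`
#' (non-negative, same length).
#'
#' @param scans list of scans as described above.
#' @param sample_id sample identifier string.
#' @param source_path path the run was read from (or `""`).
#' @param polarity,mode optional metadata strings.
#' @return an object of class `"raw_run"`.
#' @export
raw_run <- function(scans, sample_id = "sample", source_path = "",
                    polarity = NA_character_, mode = NA_character_) {
  if (length(scans) < 2L) stopf("a run needs at least 2 scans (got %d)", length(scans))
  rts <- vapply(scans, `[[`, 0, "rt")
  if (any(diff(rts) <= 0)) stopf("scan retention times must be strictly increasing")
  for (i in seq_along(scans)) {
    s <- scans[[i]]
    if (length(s$mz) != length(s$intensity)) {
      stopf("scan %d: mz and intensity lengths differ", i)
    }
    if (length(s$mz) > 1L && any(diff(s$mz) <= 0)) {
      stopf("scan %d: m/z values must be strictly ascending", i)
    }
    if (any(s$intensity < 0)) stopf("scan %d: negative intensity", i)
  }
  structure(list(scans = scans, sample_id = sample_id,
                 source_path = source_path, polarity = polarity, mode = mode),
            class = "raw_run")
}

#' @export
print.raw_run <- function(x, ...) {
  rts <- run_rts(x)
  cat(sprintf("<raw_run> '%s': %d scans, RT %.1f-%.1f s, %d-%d points/scan\n",
              x$sample_id, length(x$scans), min(rts), max(rts),
              min(vapply(x$scans, function(s) length(s$mz), 0L)),
              max(vapply(x$scans, function(s) length(s$mz), 0L))))
  invisible(x)
}

#' Scan retention times of a run
#' @param run a [raw_run()].
#' @return numeric vector of scan RTs in seconds.
#' @export
run_rts <- function(run) vapply(run$scans, `[[`, 0, "rt")

#' Total ion current of a run
#' @param run a [raw_run()].
#' @return numeric vector, summed intensity per scan.
#' @export
run_tic <- function(run) vapply(run$scans, function(s) sum(s$intensity), 0)

#' Read a raw GC-MS run
#'
#' Reads centroided runs from mzML (via the proteowizard parsers in
#' \pkg{mzR}) or ANDI-MS NetCDF (via \pkg{ncdf4}). Profile spectra are
#' accepted as-is; no centroiding is performed. Intensities are stored as
#' 64-bit floats regardless of the source encoding and m/z is reported in Th
#' without recalibration.
#'
#' @param path file path.
#' @param format `"mzml"`, `"netcdf"` or `"auto"` (resolve from extension).
#' @param sample_id sample id for the returned run; default is the file base
#'   name without extension.
#' @return a [raw_run()].
#' @export
read_raw <- function(path, format = c("auto", "mzml", "netcdf"),
                     sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      mzml = "mzml", cdf = "netcdf", nc = "netcdf",
      mzdata = stopf("unsupported format: mzData ('%s')", path),
      stopf("cannot resolve format from extension '.%s'; pass `format`", ext))
  }
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  if (format == "mzml") read_raw_mzml(path, sample_id) else read_raw_netcdf(path, sample_id)
}

read_raw_mzml <- function(path, sample_id) {
  f <- tryCatch(mzR::openMSfile(path),
                error = function(e) stopf("cannot parse mzML file '%s': %s",
                                          path, conditionMessage(e)))
  on.exit(try(mzR::close(f), silent = TRUE), add = TRUE)
  hdr <- mzR::header(f)
  n <- nrow(hdr)
  if (is.null(n) || n < 1L) stopf("no scans in '%s'", path)
  pk <- mzR::peaks(f)
  if (is.matrix(pk)) pk <- list(pk)
  scans <- vector("list", n)
  for (i in seq_len(n)) {
    m <- pk[[i]]
    scans[[i]] <- list(rt = as.double(hdr$retentionTime[i]),
                       mz = as.double(m[, 1L]), intensity = as.double(m[, 2L]))
  }
  scans <- scans[order(vapply(scans, `[[`, 0, "rt"))]
  raw_run(scans, sample_id = sample_id, source_path = path)
}

read_raw_netcdf <- function(path, sample_id) {
  nc <- tryCatch(ncdf4::nc_open(path),
                 error = function(e) stopf("cannot parse NetCDF file '%s': %s",
                                           path, conditionMessage(e)))
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  getv <- function(name) {
    if (!name %in% names(nc$var)) stopf("NetCDF file '%s' lacks variable '%s'", path, name)
    as.double(ncdf4::ncvar_get(nc, name))
  }
  rt <- getv("scan_acquisition_time")
  idx <- getv("scan_index")
  mass <- getv("mass_values")
  int <- getv("intensity_values")
  n <- length(rt)
  if (n < 1L || !length(mass)) stopf("no scans in '%s'", path)
  ends <- c(idx[-1L], length(mass))
  scans <- vector("list", n)
  for (i in seq_len(n)) {
    sel <- if (ends[i] > idx[i]) (idx[i] + 1L):ends[i] else integer(0)
    o <- order(mass[sel])
    scans[[i]] <- list(rt = rt[i], mz = mass[sel][o], intensity = int[sel][o])
  }
  raw_run(scans, sample_id = sample_id, source_path = path)
}

enc64 <- function(x) {
  gsub("[\r\n]", "",
       jsonlite::base64_enc(writeBin(as.double(x), raw(), size = 8,
                                     endian = "little")))
}

#' Write a run to mzML
#'
#' Emits a minimal plain (non-indexed) mzML 1.1.0 document with uncompressed
#' 64-bit float binary arrays; readable by standard mzML parsers.
#'
#' @param run a [raw_run()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stopf("cannot write '%s': %s", path,
                                            conditionMessage(e)))
  on.exit(close(con), add = TRUE)
  w <- function(...) cat(..., "\n", sep = "", file = con)
  n <- length(run$scans)
  w('<?xml version="1.0" encoding="utf-8"?>')
  w('<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">')
  w('<cvList count="1"><cv id="MS" fullName="PSI-MS" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/></cvList>')
  w('<fileDescription><fileContent><cvParam cvRef="MS" accession="MS:1000294" name="mass spectrum" value=""/></fileContent></fileDescription>')
  w('<softwareList count="1"><software id="peakforge" version="0.1"/></softwareList>')
  w('<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"/></instrumentConfigurationList>')
  w('<dataProcessingList count="1"><dataProcessing id="dp1"><processingMethod order="1" softwareRef="peakforge"/></dataProcessing></dataProcessingList>')
  w(sprintf('<run id="%s" defaultInstrumentConfigurationRef="IC1">', run$sample_id))
  w(sprintf('<spectrumList count="%d" defaultDataProcessingRef="dp1">', n))
  for (i in seq_len(n)) {
    s <- run$scans[[i]]
    bmz <- enc64(s$mz); bint <- enc64(s$intensity)
    w(sprintf('<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
              i - 1L, i, length(s$mz)))
    w('<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>')
    w('<cvParam cvRef="MS" accession="MS:1000294" name="mass spectrum" value=""/>')
    w('<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>')
    w('<scanList count="1"><cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/><scan>')
    w(sprintf('<cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%.8f" unitCvRef="UO" unitAccession="UO:0000010" unitName="second"/>', s$rt))
    w('</scan></scanList>')
    w('<binaryDataArrayList count="2">')
    w(sprintf('<binaryDataArray encodedLength="%d">', nchar(bmz)))
    w('<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>')
    w('<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>')
    w('<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>')
    w(sprintf('<binary>%s</binary>', bmz))
    w('</binaryDataArray>')
    w(sprintf('<binaryDataArray encodedLength="%d">', nchar(bint)))
    w('<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>')
    w('<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>')
    w('<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>')
    w(sprintf('<binary>%s</binary>', bint))
    w('</binaryDataArray></binaryDataArrayList></spectrum>')
  }
  w('</spectrumList></run></mzML>')
  invisible(path)
}

#' Write a run to ANDI-MS NetCDF
#'
#' Uses the standard ANDI-MS variable layout (`scan_acquisition_time`,
#' `scan_index`, `point_count`, `mass_values`, `intensity_values`,
#' `total_intensity`) with double precision throughout.
#'
#' @param run a [raw_run()].
#' @param path output `.cdf` path.
#' @return `path`, invisibly.
#' @export
write_netcdf <- function(run, path) {
  counts <- vapply(run$scans, function(s) length(s$mz), 0L)
  npts <- sum(counts)
  dscan <- ncdf4::ncdim_def("scan_number", "", seq_along(run$scans),
                            create_dimvar = FALSE)
  dpoint <- ncdf4::ncdim_def("point_number", "", seq_len(max(npts, 1L)),
                             create_dimvar = FALSE)
  vars <- list(
    ncdf4::ncvar_def("scan_acquisition_time", "seconds", dscan, prec = "double"),
    ncdf4::ncvar_def("scan_index", "", dscan, prec = "integer"),
    ncdf4::ncvar_def("point_count", "", dscan, prec = "integer"),
    ncdf4::ncvar_def("total_intensity", "counts", dscan, prec = "double"),
    ncdf4::ncvar_def("mass_values", "m/z", dpoint, prec = "double"),
    ncdf4::ncvar_def("intensity_values", "counts", dpoint, prec = "double"))
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  ncdf4::ncvar_put(nc, "scan_acquisition_time", run_rts(run))
  ncdf4::ncvar_put(nc, "scan_index", cumsum(c(0L, counts[-length(counts)])))
  ncdf4::ncvar_put(nc, "point_count", counts)
  ncdf4::ncvar_put(nc, "total_intensity", run_tic(run))
  ncdf4::ncvar_put(nc, "mass_values", unlist(lapply(run$scans, `[[`, "mz")))
  ncdf4::ncvar_put(nc, "intensity_values",
                   unlist(lapply(run$scans, `[[`, "intensity")))
  invisible(path)
}
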