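#' Construct a spectral library record
#'
#' @param name compound name.
#' @param peaks two-column matrix or data frame of (mz, relative intensity);
#'   intensities are max-normalised to 1.0 on construction.
#' @param ri optional retention index.
#' @return an object of class `"spectrum_record"`.
#' @export
spectrum_record <- function(name, peaks, ri = NA_real_) {
  peaks <- as.matrix(peaks)
  if (nrow(peaks) < 1L) stopf("record '%s': empty spectrum", name)
  if (any(peaks[, 2L] <= 0)) stopf("record '%s': intensities must be > 0", name)
  o <- order(peaks[, 1L])
  structure(list(name = name, ri = as.double(ri),
                 mz = as.double(peaks[o, 1L]),
                 intensity = as.double(peaks[o, 2L]) / max(peaks[, 2L])),
            class = "spectrum_record")
}

#' Read a NIST-dialect MSP spectral library
#'
#' Parses `Name:`, optional `Retention_index:`/`RI:` and `RT:` headers and
#' `Num Peaks:` blocks of whitespace- or semicolon-separated (mz, intensity)
#' pairs. Intensities on any positive scale are accepted and max-normalised
#' to 1.0.
#'
#' @param path MSP file path.
#' @return list of [spectrum_record()] objects.
#' @export
read_msp <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  records <- list()
  name <- NULL; ri <- NA_real_; rt <- NA_real_; npk <- NA_integer_; pairs <- NULL
  flush <- function() {
    if (is.null(name)) return()
    if (is.na(npk)) stopf("record '%s': missing 'Num Peaks'", name)
    got <- if (is.null(pairs)) 0L else nrow(pairs)
    if (got != npk) {
      stopf("record '%s': 'Num Peaks: %d' but %d pairs listed", name, npk, got)
    }
    rec <- spectrum_record(name, pairs, ri = ri)
    rec$rt <- rt
    records[[length(records) + 1L]] <<- rec
    name <<- NULL; ri <<- NA_real_; rt <<- NA_real_
    npk <<- NA_integer_; pairs <<- NULL
  }
  for (line in lines) {
    line <- trimws(line)
    if (line == "") { flush(); next }
    if (grepl("^Name:", line, ignore.case = TRUE)) {
      flush()
      name <- trimws(sub("^Name:", "", line, ignore.case = TRUE))
    } else if (grepl("^(Retention_index|RI):", line, ignore.case = TRUE)) {
      ri <- as.double(trimws(sub("^[^:]*:", "", line)))
    } else if (grepl("^RT:", line, ignore.case = TRUE)) {
      rt <- as.double(trimws(sub("^[^:]*:", "", line)))
    } else if (grepl("^Num Peaks:", line, ignore.case = TRUE)) {
      npk <- as.integer(trimws(sub("^Num Peaks:", "", line, ignore.case = TRUE)))
    } else if (grepl(":", line) && is.na(npk)) {
      next  # unrecognised header field
    } else if (!is.na(npk)) {
      toks <- strsplit(line, "[;,[:space:]]+")[[1]]
      toks <- toks[toks != ""]
      if (length(toks) %% 2L != 0L) {
        stopf("record '%s': malformed peak line '%s'", name %||% "?", line)
      }
      v <- as.double(toks)
      pairs <- rbind(pairs, matrix(v, ncol = 2L, byrow = TRUE))
    }
  }
  flush()
  records
}

#' Write features to a NIST-dialect MSP file
#'
#' One record per feature: `Name`, `RT`, optional `RI`, `Num Peaks` and the
#' (mz, intensity) pairs, intensity scaled to a maximum of 999 and rounded
#' to integers (NIST convention). Records are separated by a blank line.
#'
#' @param x a `final_peak_set`, `feature_table` or list of [gc_peak()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msp <- function(x, path) {
  feats <- as_feature_list(x)
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stopf("cannot write '%s': %s", path,
                                            conditionMessage(e)))
  on.exit(close(con), add = TRUE)
  for (f in feats) {
    if (!length(f$mz) || all(f$height <= 0)) {
      stopf("feature '%s': empty spectrum, cannot write MSP record", f$id)
    }
    cat(sprintf("Name: %s\n", f$id), file = con)
    cat(sprintf("RT: %.3f\n", f$rt_apex), file = con)
    if (!is.null(f$ri) && !is.na(f$ri)) {
      cat(sprintf("Retention_index: %.2f\n", f$ri), file = con)
    }
    cat(sprintf("Num Peaks: %d\n", length(f$mz)), file = con)
    sc <- pmax(1L, as.integer(round(f$height / max(f$height) * 999)))
    cat(paste(sprintf("%.4f %d", f$mz, sc), collapse = "\n"), "\n\n",
        sep = "", file = con)
  }
  invisible(path)
}

#' Write the feature CSV
#'
#' One row per feature with the schema: `feature_id, rt_apex_s, rt_start_s,
#' rt_end_s, ri, n_mz, class_label, source_algorithms`, then one absolute
#' apex-intensity column per sample (summed over the feature's m/z list).
#' Comma-separated, `.` decimal, UTF-8, mandatory header. Integrated areas
#' are written alongside as `<path base>_area.csv` when `areas = TRUE`.
#'
#' @param x a `final_peak_set`, `feature_table` or list of [gc_peak()].
#' @param path output CSV path.
#' @param areas also write the area-variant table.
#' @return `path`, invisibly.
#' @export
write_peak_csv <- function(x, path, areas = FALSE) {
  tab <- as_feature_csv(x)
  ok <- tryCatch({
    utils::write.csv(tab$height, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8", na = "")
    TRUE
  }, error = function(e) stopf("cannot write '%s': %s", path, conditionMessage(e)))
  if (areas && !is.null(tab$area)) {
    apath <- sub("(\\.csv)?$", "_area.csv", path)
    utils::write.csv(tab$area, apath, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8", na = "")
  }
  invisible(path)
}

# ---- internal coercions -----------------------------------------------------

# normalise the various containers to a list of feature records with fields
# id, rt_apex, rt_start, rt_end, ri, mz, height, area, class_label,
# algorithms, intensities (named per-sample summed apex heights)
as_feature_list <- function(x) {
  if (inherits(x, "final_peak_set")) x <- x$high
  # already a list of plain feature records
  if (is.list(x) && length(x) && !inherits(x[[1]], "gc_peak") &&
      !inherits(x, "feature_table") &&
      all(c("id", "mz", "height") %in% names(x[[1]]))) {
    return(lapply(x, function(f) {
      f$intensities <- f$intensities %||% stats::setNames(sum(f$height), "sample")
      f$areas_by_sample <- f$areas_by_sample %||% f$intensities
      f
    }))
  }
  if (inherits(x, "feature_table")) {
    feats <- vector("list", nrow(x$features))
    for (i in seq_along(feats)) {
      p <- x$peaks[[i]]
      feats[[i]] <- list(id = x$features$feature_id[i], rt_apex = p$rt_apex,
                         rt_start = p$rt_start, rt_end = p$rt_end,
                         ri = x$features$ri[i], mz = p$mz, height = p$height,
                         area = p$area, class_label = p$class_label,
                         algorithms = p$provenance$algorithms,
                         intensities = x$height[i, , drop = TRUE],
                         areas_by_sample = x$area[i, , drop = TRUE])
    }
    return(feats)
  }
  # plain list of gc_peak
  lapply(seq_along(x), function(i) {
    p <- x[[i]]
    inten <- sum(p$height); names(inten) <- p$sample_id
    ar <- sum(p$area); names(ar) <- p$sample_id
    list(id = if (!is.na(p$id)) p$id else sprintf("F%04d", i),
         rt_apex = p$rt_apex, rt_start = p$rt_start, rt_end = p$rt_end,
         ri = p$ri %||% NA_real_, mz = p$mz, height = p$height, area = p$area,
         class_label = p$class_label, algorithms = p$provenance$algorithms,
         intensities = inten, areas_by_sample = ar)
  })
}

as_feature_csv <- function(x) {
  feats <- as_feature_list(x)
  samples <- sort(unique(unlist(lapply(feats, function(f) names(f$intensities)))))
  base_cols <- data.frame(
    feature_id = vapply(feats, `[[`, "", "id"),
    rt_apex_s = round(vapply(feats, `[[`, 0, "rt_apex"), 3),
    rt_start_s = round(vapply(feats, `[[`, 0, "rt_start"), 3),
    rt_end_s = round(vapply(feats, `[[`, 0, "rt_end"), 3),
    ri = vapply(feats, function(f) as.double(f$ri %||% NA_real_), 0),
    n_mz = vapply(feats, function(f) length(f$mz), 0L),
    class_label = vapply(feats, function(f) f$class_label %||% NA_character_, ""),
    source_algorithms = vapply(feats, function(f) paste(f$algorithms, collapse = ";"), ""),
    stringsAsFactors = FALSE)
  if (!length(feats)) {
    base_cols <- data.frame(feature_id = character(0), rt_apex_s = numeric(0),
                            rt_start_s = numeric(0), rt_end_s = numeric(0),
                            ri = numeric(0), n_mz = integer(0),
                            class_label = character(0),
                            source_algorithms = character(0),
                            stringsAsFactors = FALSE)
  }
  fill <- function(field) {
    m <- matrix(0, nrow = length(feats), ncol = length(samples),
                dimnames = list(NULL, samples))
    for (i in seq_along(feats)) {
      v <- feats[[i]][[field]]
      m[i, names(v)] <- as.double(v)
    }
    as.data.frame(m)
  }
  list(height = cbind(base_cols, fill("intensities")),
       area = cbind(base_cols, fill("areas_by_sample")))
}
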