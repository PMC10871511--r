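#' Read a plain-text peak list
#'
#' Parses whitespace- or tab-delimited centroided peak data: one peak per
#' line, m/z then intensity. Lines starting with `#` are ignored. Column
#' positions are configurable to accommodate exports with extra columns.
#'
#' @param path File path.
#' @param mz_col,intensity_col 1-based column indices.
#' @param source_label Label stored with the peak list; defaults to the
#'   file name.
#' @return A `peak_list`: data frame with columns `mz` and `intensity` in
#'   input order, with attributes `source_label` and (derived)
#'   `base_peak_intensity`.
#' @export
read_peak_list <- function(path, mz_col = 1L, intensity_col = 2L,
                           source_label = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) {
    warning("empty peak list: ", path, call. = FALSE)
    return(peak_list(numeric(0), numeric(0), source_label))
  }
  mz <- numeric(length(keep))
  int <- numeric(length(keep))
  for (k in seq_along(keep)) {
    fields <- strsplit(trimws(lines[[keep[[k]]]]), "\\s+")[[1L]]
    if (length(fields) < max(mz_col, intensity_col)) {
      stop("line ", keep[[k]], " of ", path, ": expected at least ",
           max(mz_col, intensity_col), " columns", call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(fields[c(mz_col, intensity_col)]))
    if (anyNA(v)) {
      stop("line ", keep[[k]], " of ", path, ": non-numeric field",
           call. = FALSE)
    }
    mz[[k]] <- v[[1L]]
    int[[k]] <- v[[2L]]
  }
  peak_list(mz, int, source_label)
}

#' Construct a peak list
#'
#' @param mz,intensity Numeric vectors; m/z must be positive and intensity
#'   non-negative.
#' @param source_label Text label.
#' @return A `peak_list`.
#' @export
peak_list <- function(mz, intensity, source_label = "peaks") {
  if (length(mz) != length(intensity)) {
    stop("mz and intensity must have equal length", call. = FALSE)
  }
  if (length(mz) && (any(mz <= 0) || any(intensity < 0))) {
    stop("peaks require mz > 0 and intensity >= 0", call. = FALSE)
  }
  structure(data.frame(mz = as.numeric(mz),
                       intensity = as.numeric(intensity)),
            source_label = source_label,
            class = c("peak_list", "data.frame"))
}

#' @rdname peak_list
#' @param x A `peak_list`.
#' @return `base_peak_intensity()`: the maximum intensity (0 for an empty
#'   list).
#' @export
base_peak_intensity <- function(x) {
  if (nrow(x) == 0L) 0 else max(x$intensity)
}

#' Read a contaminant m/z list
#'
#' One m/z value per line, `#` comments allowed. The package ships the
#' characteristic peak lists of four peptide-synthesis protecting-group
#' standards (Fmoc-Cl, Trt-Cl, Pbf-Cl, Boc/OtBu) under
#' `extdata/contaminants/`; [contaminant_list()] loads them by name.
#'
#' @param path File path.
#' @param label Text label; defaults to the file name.
#' @return Numeric vector of unique positive m/z values with a `label`
#'   attribute.
#' @export
read_contaminants <- function(path, label = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  v <- suppressWarnings(as.numeric(trimws(lines[keep])))
  if (anyNA(v)) {
    stop("non-numeric contaminant value on line ",
         keep[which(is.na(v))[1L]], " of ", path, call. = FALSE)
  }
  if (any(v <= 0) || anyDuplicated(v)) {
    stop("contaminant m/z values must be positive and unique",
         call. = FALSE)
  }
  structure(v, label = label)
}

#' @rdname read_contaminants
#' @param name One of `"fmoc"`, `"trt"`, `"pbf"`, `"boc"`.
#' @export
contaminant_list <- function(name = c("fmoc", "trt", "pbf", "boc")) {
  name <- match.arg(name)
  read_contaminants(system.file("extdata", "contaminants",
                                paste0(name, ".txt"), package = "eifrag",
                                mustWork = TRUE),
                    label = name)
}

#' Write an annotated spectrum
#'
#' Tab-separated output with one row per observed peak: m/z, intensity and
#' an annotation column carrying the matched fragment's mechanism path,
#' a `contaminant` flag, and a `base_peak` flag on the single most intense
#' peak. Unannotated peaks get `background`.
#'
#' @param matches A `match_report` from [match_peaks()].
#' @param path Output file path.
#' @export
write_annotated <- function(matches, path) {
  df <- as.data.frame(matches)
  ann <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    parts <- character(0)
    if (df$class[[i]] == "contaminant") parts <- "contaminant"
    if (df$class[[i]] == "matched") parts <- df$annotation[[i]]
    if (length(parts) == 0L) parts <- "background"
    if (i == which.max(df$intensity)) parts <- c(parts, "base_peak")
    ann[[i]] <- paste(parts, collapse = "; ")
  }
  out <- data.frame(mz = sprintf("%.4f", df$mz),
                    intensity = sprintf("%.4f", df$intensity),
                    annotation = ann, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  # header as a comment so annotated files re-parse as peak lists
  writeLines("# mz\tintensity\tannotation", con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
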