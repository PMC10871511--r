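#' Seeded synthetic EI spectrum generator
#'
#' Builds a reproducible synthetic peak list emulating a crude-sample
#' DEP-EI spectrum of a peptide: a sampled fraction of the sequence's own
#' predicted fragment peaks with small Gaussian m/z jitter, optional
#' protecting-group contaminant peaks, and uniform-random background peaks
#' within the instrument scan range. It exists so every downstream stage
#' (matching, masking, scoring) is testable end-to-end without instrument
#' data; it does not emulate realistic relative intensities, isotope
#' envelopes, or peak-shape effects.
#'
#' @param sequence Peptide sequence (one-letter codes).
#' @param seed Integer seed; the generator never touches the global RNG
#'   state.
#' @param fraction_observed Fraction of predicted fragments planted as
#'   observed peaks, in (0, 1].
#' @param mz_jitter_sd Gaussian jitter SD in m/z units; keep at or below a
#'   third of the matching tolerance so planted peaks remain matchable
#'   (default 0.05 against the 0.25 tolerance).
#' @param n_background Number of uniform-random background peaks.
#' @param contaminant_set Optional name of a shipped protecting-group list
#'   (`"fmoc"`, `"trt"`, `"pbf"`, `"boc"`) whose peaks are injected.
#' @param intensity_model Only `"log-uniform"` is implemented: decadic
#'   log-intensities drawn uniformly, planted fragment peaks over 1e5--1e8
#'   counts (the scale of typical DEP-EI base peaks), background one decade
#'   lower.
#' @param scan_range Length-2 numeric; observed peaks outside the
#'   instrument scan window (default 60--350 m/z) are discarded, mirroring
#'   acquisition settings. Predictions themselves are never clamped.
#' @param catalogue Mechanism catalogue used for the underlying
#'   predictions.
#' @return A `peak_list`.
#' @examples
#' pk <- simulate_spectrum("QFA", seed = 1, fraction_observed = 1,
#'                         mz_jitter_sd = 0, n_background = 0)
#' score_spectrum(pk, enumerate_fragments("QFA"), 0.05)$percent_matched
#' @export
simulate_spectrum <- function(sequence, seed,
                              fraction_observed = 0.8,
                              mz_jitter_sd = 0.05,
                              n_background = 15L,
                              contaminant_set = NULL,
                              intensity_model = "log-uniform",
                              scan_range = c(60, 350),
                              catalogue = builtin_catalogue()) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L ||
      is.na(seed)) {
    stop("invalid config field 'seed': must be a single integer",
         call. = FALSE)
  }
  if (!is.numeric(fraction_observed) || length(fraction_observed) != 1L ||
      fraction_observed <= 0 || fraction_observed > 1) {
    stop("invalid config field 'fraction_observed': must be in (0, 1]",
         call. = FALSE)
  }
  if (!is.numeric(mz_jitter_sd) || length(mz_jitter_sd) != 1L ||
      mz_jitter_sd < 0) {
    stop("invalid config field 'mz_jitter_sd': must be >= 0",
         call. = FALSE)
  }
  if (!is.numeric(n_background) || length(n_background) != 1L ||
      n_background < 0 || n_background != round(n_background)) {
    stop("invalid config field 'n_background': must be a non-negative ",
         "integer", call. = FALSE)
  }
  if (!identical(intensity_model, "log-uniform")) {
    stop("invalid config field 'intensity_model': only 'log-uniform' is ",
         "implemented", call. = FALSE)
  }
  if (!is.numeric(scan_range) || length(scan_range) != 2L ||
      scan_range[[1L]] <= 0 || scan_range[[2L]] <= scan_range[[1L]]) {
    stop("invalid config field 'scan_range': need increasing positive ",
         "pair", call. = FALSE)
  }

  ps <- enumerate_fragments(sequence, catalogue)

  state <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(state)) assign(".Random.seed", state, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))

  n_take <- max(1L, ceiling(fraction_observed * length(ps$mz)))
  take <- sort(sample.int(length(ps$mz), n_take))
  mz <- ps$mz[take] + stats::rnorm(n_take, 0, mz_jitter_sd)
  int <- 10^stats::runif(n_take, 5, 8)

  if (!is.null(contaminant_set)) {
    cm <- contaminant_list(contaminant_set)
    mz <- c(mz, as.numeric(cm))
    int <- c(int, 10^stats::runif(length(cm), 5, 7.5))
  }
  if (n_background > 0L) {
    mz <- c(mz, stats::runif(n_background, scan_range[[1L]],
                             scan_range[[2L]]))
    int <- c(int, 10^stats::runif(n_background, 4, 7))
  }
  keep <- mz >= scan_range[[1L]] & mz <= scan_range[[2L]]
  # the intact molecular ion of short peptides can exceed the scan window;
  # synthetic observations honor the window, predictions are untouched
  o <- order(mz[keep])
  peak_list(mz[keep][o], int[keep][o],
            source_label = sprintf("synthetic:%s:seed%d", sequence,
                                   as.integer(seed)))
}

#' Read a fixture configuration file
#'
#' Plain-text key-value pairs, one `key = value` per line, `#` comments
#' allowed. Recognized keys mirror the arguments of
#' [simulate_spectrum()]; `scan_range` is given as `lo,hi`.
#'
#' @param path File path.
#' @return Named list of parsed options.
#' @export
read_fixture_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  out <- list()
  numeric_keys <- c("seed", "fraction_observed", "mz_jitter_sd",
                    "n_background")
  for (ln in keep) {
    m <- regmatches(lines[[ln]],
                    regexec("^\\s*([A-Za-z_]+)\\s*=\\s*(.+?)\\s*$",
                            lines[[ln]]))[[1L]]
    if (length(m) != 3L) {
      stop("malformed config line ", ln, " in ", path, call. = FALSE)
    }
    key <- m[[2L]]; val <- m[[3L]]
    out[[key]] <- if (key %in% numeric_keys) {
      as.numeric(val)
    } else if (key == "scan_range") {
      as.numeric(strsplit(val, ",")[[1L]])
    } else {
      val
    }
  }
  out
}
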