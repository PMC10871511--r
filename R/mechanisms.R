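#' Fragmentation-mechanism catalogues
#'
#' A catalogue is a table of fragmentation events. Each entry has:
#'
#' * `residues` -- the one-letter codes the event applies to, or `"CTERM"`
#'   for degradations of the original C-terminal carboxyl;
#' * `label` -- free text naming the event. Flag words are reserved:
#'   `"type"` never appears in labels (it marks backbone cleavage in path
#'   records); `"side"` in a label marks a side-chain event; a
#'   residue-scoped relative event *without* `"side"` in its label is
#'   C-terminal-associated and fires only paired with a C-terminal loss
#'   (the alkene-formation mechanism of Lys/Pro/Ile);
#' * `kind` -- `"relative"` for a neutral/radical loss subtracted from the
#'   parent (an M-x change), `"charged"` for a non-relative event whose
#'   payload *is* the detected ion: its m/z never depends on the parent and
#'   it seeds no further fragmentation;
#' * `payload` -- an elemental composition: the loss (charge 0) or the ion
#'   (charge +1).
#'
#' @name mech_catalogue
NULL

new_catalogue <- function(residues, label, kind, payload, provenance) {
  stopifnot(length(residues) == length(label),
            length(label) == length(kind),
            length(kind) == length(payload))
  scope <- ifelse(residues == "CTERM", "cterm",
           ifelse(grepl("side", label, fixed = TRUE), "side", "cterm-paired"))
  out <- data.frame(residues = residues, label = label, kind = kind,
                    scope = scope, stringsAsFactors = FALSE)
  out$payload <- payload
  key <- paste(out$label, out$residues)
  if (anyDuplicated(key)) {
    stop("duplicate (label, residues) entry in mechanism catalogue",
         call. = FALSE)
  }
  structure(out, provenance = provenance,
            class = c("mech_catalogue", "data.frame"))
}

#' Built-in mechanism catalogue
#'
#' The side-chain and C-terminal fragmentation events confirmed for
#' unfunctionalized amino acids under direct-exposure-probe EI: ammonia loss
#' from the amide residues, beta-elimination from the alcohol/thiol
#' residues, whole and partial carboxyl losses from the acidic side chains
#' and from the C-terminus, Met's partial side-chain loss, the generic
#' lost-side-chain event (per-residue payload), Lys side-chain cyclization,
#' alkene formation for Lys/Pro/Ile (fires only alongside a C-terminal
#' loss), the Arg guanidino losses, and the non-relative charged side-chain
#' ions of Phe, Tyr, Trp, His, Met and Leu.
#'
#' Glycine carries no side-chain events. Ala, Gly, Pro and Tyr are absent
#' from the generic lost-side-chain residue list; users can widen it through
#' a definition file (see [read_mechanisms()]).
#'
#' @return A `mech_catalogue`.
#' @examples
#' cat <- builtin_catalogue()
#' subset(cat, residues == "M")
#' @export
builtin_catalogue <- function() {
  rt <- residue_table()
  res <- character(0); lab <- character(0); kind <- character(0)
  pay <- list()
  add <- function(r, l, k, p) {
    res <<- c(res, r); lab <<- c(lab, l); kind <<- c(kind, k)
    pay[[length(pay) + 1L]] <<- p
  }
  rel <- function(r, l, p) add(r, l, "relative", p)
  chg <- function(r, l, p) add(r, l, "charged", p)

  for (r in c("N", "Q")) rel(r, "side ammonia loss", AMMONIA)
  for (r in c("S", "T")) rel(r, "side beta elimination", WATER)
  rel("C", "side beta elimination", composition(h_count = 2L, s_count = 1L))
  for (r in c("D", "E")) {
    rel(r, "side carboxylic acid whole", CO2H)
    rel(r, "side carboxylic acid partial radical", HYDROXYL)
    rel(r, "side carboxylic acid partial", WATER)
  }
  rel("M", "side partial chain loss",
      composition(2L, 5L, s_count = 1L))
  for (r in c("C", "D", "E", "F", "H", "I", "K", "L", "M", "N",
              "Q", "R", "S", "T", "V", "W")) {
    rel(r, "side chain loss", rt$side_chain[[residue_lookup(r, rt)]])
  }
  rel("K", "side chain cyclization", AMMONIA)
  for (r in c("K", "P", "I")) rel(r, "alkene formation", H_ATOM)
  rel("R", "side partial guanidino loss", composition(1L, 2L, 2L))
  rel("R", "side guanidino loss alkene", composition(1L, 6L, 3L))

  rel("CTERM", "carboxylic acid whole", CO2H)
  rel("CTERM", "carboxylic acid partial radical", HYDROXYL)
  rel("CTERM", "carboxylic acid partial", WATER)

  ion <- function(c, h, n = 0L, o = 0L, s = 0L)
    composition(c, h, n, o, s, charge = 1L)
  chg("F", "charged side chain loss", ion(7L, 7L))
  chg("F", "charged side chain loss alkene", ion(8L, 7L))
  chg("Y", "charged side chain loss", ion(7L, 7L, o = 1L))
  chg("Y", "charged side chain loss alkene", ion(8L, 7L, o = 1L))
  chg("W", "charged side chain loss", ion(9L, 8L, 1L))
  chg("H", "charged side chain loss", ion(4L, 5L, 2L))
  chg("H", "charged side chain loss alkene", ion(5L, 5L, 2L))
  chg("H", "charged side chain loss radical", ion(4L, 6L, 2L))
  chg("M", "charged side chain loss", ion(3L, 7L, s = 1L))
  chg("M", "charged side chain methylene sub frag loss", ion(2L, 5L, s = 1L))
  chg("L", "charged side chain loss", ion(4L, 9L))

  new_catalogue(res, lab, kind, pay, provenance = "built-in")
}

#' Read a mechanism definition file
#'
#' Parses the plain-text mechanism dialect so the catalogue can be extended
#' or replaced without code changes. One record per line, fields separated
#' by `" | "`:
#'
#' ```
#' residues | label | kind | C,H,N,O,S,z
#' ```
#'
#' `residues` is one or more concatenated one-letter codes (the entry is
#' expanded to one per residue), or `CTERM`. `kind` is `relative` or
#' `charged`. Lines starting with `#` and blank lines are ignored. Labels
#' containing the reserved word `type` are rejected; relative payloads must
#' have charge 0 and charged payloads charge +1.
#'
#' The shipped file `extdata/mechanisms.txt` reproduces
#' [builtin_catalogue()] exactly.
#'
#' @param path File path.
#' @param table Residue table used to validate codes.
#' @return A `mech_catalogue` with provenance set to `path`.
#' @export
read_mechanisms <- function(path, table = residue_table()) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  res <- character(0); lab <- character(0); kind <- character(0)
  pay <- list()
  for (ln in keep) {
    fields <- strsplit(trimws(lines[[ln]]), "\\s*\\|\\s*")[[1L]]
    if (length(fields) != 4L) {
      stop("malformed mechanism record on line ", ln, ": expected 4 ",
           "'|'-separated fields, got ", length(fields), call. = FALSE)
    }
    rcodes <- fields[[1L]]
    label <- fields[[2L]]
    knd <- fields[[3L]]
    if (grepl("type", label, fixed = TRUE)) {
      stop("line ", ln, ": label contains the reserved word 'type' ",
           "(reserved for backbone cleavage)", call. = FALSE)
    }
    if (!knd %in% c("relative", "charged")) {
      stop("line ", ln, ": kind must be 'relative' or 'charged', got '",
           knd, "'", call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(strsplit(fields[[4L]], ",")[[1L]]))
    if (length(v) != 6L || anyNA(v)) {
      stop("line ", ln, ": formula field must be six comma-separated ",
           "integers C,H,N,O,S,z", call. = FALSE)
    }
    p <- composition(v[1L], v[2L], v[3L], v[4L], v[5L], v[6L])
    if (knd == "relative" && p[["z"]] != 0L) {
      stop("line ", ln, ": relative payloads must be neutral (z = 0)",
           call. = FALSE)
    }
    if (knd == "charged" && p[["z"]] != 1L) {
      stop("line ", ln, ": charged payloads must carry charge +1",
           call. = FALSE)
    }
    if (rcodes == "CTERM") {
      codes <- "CTERM"
    } else {
      codes <- strsplit(rcodes, "")[[1L]]
      if (!all(codes %in% table$code)) {
        stop("line ", ln, ": unknown residue code '",
             setdiff(codes, table$code)[1L], "'", call. = FALSE)
      }
    }
    for (cd in codes) {
      res <- c(res, cd); lab <- c(lab, label); kind <- c(kind, knd)
      pay[[length(pay) + 1L]] <- p
    }
  }
  new_catalogue(res, lab, kind, pay, provenance = path)
}

#' @rdname read_mechanisms
#' @param catalogue A `mech_catalogue` to serialize.
#' @export
write_mechanisms <- function(catalogue, path) {
  hdr <- c("# Fragmentation mechanism definitions.",
           "# residues | label | kind | C,H,N,O,S,z")
  rows <- vapply(seq_len(nrow(catalogue)), function(i) {
    p <- unclass(catalogue$payload[[i]])
    paste(catalogue$residues[[i]], catalogue$label[[i]],
          catalogue$kind[[i]], paste(p, collapse = ","), sep = " | ")
  }, "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Nominal m/z change of relative mechanisms
#'
#' The approximate M-x change of a relative loss: minus the monoisotopic
#' payload mass rounded to the nearest integer (ammonia loss is M-17,
#' beta-elimination M-18 or M-34, whole carboxyl loss M-45, ...).
#'
#' @param catalogue A `mech_catalogue` (or subset of its rows); all entries
#'   must be of kind `relative`.
#' @return Integer vector of signed nominal deltas, one per entry.
#' @examples
#' cat <- builtin_catalogue()
#' nominal_delta(subset(cat, label == "side ammonia loss"))   # -17 -17
#' @export
nominal_delta <- function(catalogue) {
  if (any(catalogue$kind != "relative")) {
    stop("nominal_delta is defined for relative (M-x) events only",
         call. = FALSE)
  }
  -as.integer(round(vapply(catalogue$payload, monoisotopic_mass, 0)))
}

catalogue_provenance <- function(catalogue) {
  attr(catalogue, "provenance") %||% "unknown"
}

`%||%` <- function(a, b) if (is.null(a)) b else a
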