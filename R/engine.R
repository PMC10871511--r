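new_fragment <- function(codes, labels, composition, path, has_cterm,
                         side_used) {
  structure(list(codes = codes, labels = labels, composition = composition,
                 path = path, has_cterm = has_cterm, side_used = side_used),
            class = "pep_fragment")
}

#' @export
print.pep_fragment <- function(x, ...) {
  cat(sprintf("<pep_fragment %s  m/z %.4f  [%s]>\n",
              format_composition(x$composition),
              monoisotopic_mass(x$composition),
              if (length(x$path)) paste(x$path, collapse = " > ")
              else "intact"))
  invisible(x)
}

# neutral composition of a residue span assembled as a peptide
span_composition <- function(codes, table) {
  if (length(codes) == 0L) return(composition())
  comp <- composition()
  for (i in residue_lookup(codes, table)) {
    comp <- comp_add(comp, table$free[[i]])
  }
  n <- length(codes)
  comp_subtract(comp, composition(h_count = 2L * (n - 1L),
                                  o_count = n - 1L))
}

neutralize <- function(comp) {
  comp[["z"]] <- 0L
  comp
}

cationize <- function(comp) {
  comp[["z"]] <- 1L
  comp
}

subfragment <- function(f, idx, comp, label, has_cterm) {
  new_fragment(codes = f$codes[idx], labels = f$labels[idx],
               composition = cationize(comp),
               path = c(f$path, label),
               has_cterm = has_cterm,
               side_used = f$side_used[idx])
}

#' Backbone cleavage of a peptide fragment
#'
#' The three backbone cuts observed in EI spectra of peptides, each emitting
#' both complementary pieces as candidate cations (which piece retains the
#' charge is not modeled; the fingerprint is exhaustive by design). Cleavage
#' is homolytic with no hydrogen rearrangement: each piece keeps exactly the
#' atoms on its side of the severed bond.
#'
#' * **Type A** cuts between a residue's alpha-carbon and its carbonyl
#'   carbon, at every position. For a single free amino acid the
#'   N-terminal-side piece is the M-45 loss of the carboxyl radical.
#' * **Type B** cuts each peptide bond, giving an acylium-type N-terminal
#'   piece (keeps the carbonyl) and an amine-type C-terminal piece.
#' * **Type C** cuts between the backbone nitrogen and the alpha-carbon,
#'   only at aromatic positions (Phe, Trp, Tyr); the nitrogen and its
#'   hydrogen stay with the N-terminal piece.
#'
#' @param f A `pep_fragment`.
#' @return List of `pep_fragment` pieces (may include residue-less pieces,
#'   e.g. the bare carboxyl radical; [enumerate_fragments()] drops those
#'   from the prediction pool since a detected fragment is modeled as a
#'   residue chain).
#' @export
cleave_type_a <- function(f) {
  n <- length(f$codes)
  if (n < 1L) return(list())
  table <- residue_table()
  parent <- neutralize(f$composition)
  out <- list()
  for (i in seq_len(n)) {
    nn <- comp_subtract(span_composition(f$codes[seq_len(i)], table), CO2H)
    lab <- paste0("typeA@", f$labels[[i]])
    out[[length(out) + 1L]] <-
      subfragment(f, seq_len(i), nn, lab, has_cterm = FALSE)
    out[[length(out) + 1L]] <-
      subfragment(f, setdiff(seq_len(n), seq_len(i)),
                  comp_subtract(parent, nn), lab, has_cterm = f$has_cterm)
  }
  out
}

#' @rdname cleave_type_a
#' @export
cleave_type_b <- function(f) {
  n <- length(f$codes)
  if (n < 2L) return(list())
  table <- residue_table()
  parent <- neutralize(f$composition)
  out <- list()
  for (i in seq_len(n - 1L)) {
    nn <- comp_subtract(span_composition(f$codes[seq_len(i)], table),
                        HYDROXYL)
    lab <- paste0("typeB@", f$labels[[i]], "-", f$labels[[i + 1L]])
    out[[length(out) + 1L]] <-
      subfragment(f, seq_len(i), nn, lab, has_cterm = FALSE)
    out[[length(out) + 1L]] <-
      subfragment(f, (i + 1L):n, comp_subtract(parent, nn), lab,
                  has_cterm = f$has_cterm)
  }
  out
}

#' @rdname cleave_type_a
#' @export
cleave_type_c <- function(f) {
  n <- length(f$codes)
  table <- residue_table()
  parent <- neutralize(f$composition)
  out <- list()
  for (i in seq_len(n)) {
    if (!f$codes[[i]] %in% c("F", "W", "Y")) next
    nn <- if (i == 1L) {
      composition(h_count = 2L, n_count = 1L)
    } else {
      comp_add(comp_subtract(span_composition(f$codes[seq_len(i - 1L)],
                                              table), HYDROXYL),
               composition(h_count = 1L, n_count = 1L))
    }
    lab <- paste0("typeC@", f$labels[[i]])
    out[[length(out) + 1L]] <-
      subfragment(f, seq_len(i - 1L), nn, lab, has_cterm = FALSE)
    out[[length(out) + 1L]] <-
      subfragment(f, i:n, comp_subtract(parent, nn), lab,
                  has_cterm = f$has_cterm)
  }
  out
}

#' C-terminal carboxyl degradations
#'
#' Applies each C-terminus-scoped relative event of the catalogue (whole
#' carboxyl loss M-45, hydroxyl radical loss M-17, water loss M-18) to a
#' fragment that still carries the original C-terminal carboxyl. For
#' fragments containing Lys, Pro or Ile, each event is additionally paired
#' with alkene formation (-H) at that residue -- the combined whole loss is
#' the observed M-46 -- consuming the residue's single side-event slot.
#' All three degradations consume the carboxyl, so children are ineligible
#' for further C-terminal events.
#'
#' @param f A `pep_fragment` with `has_cterm = TRUE` (otherwise an empty
#'   list is returned).
#' @param catalogue A `mech_catalogue`.
#' @return List of `pep_fragment`s.
#' @export
apply_cterm_events <- function(f, catalogue = builtin_catalogue()) {
  if (!isTRUE(f$has_cterm)) return(list())
  ct <- which(catalogue$scope == "cterm" & catalogue$kind == "relative")
  paired <- which(catalogue$scope == "cterm-paired" &
                  catalogue$kind == "relative")
  out <- list()
  for (j in ct) {
    child <- new_fragment(
      codes = f$codes, labels = f$labels,
      composition = comp_subtract(f$composition, catalogue$payload[[j]]),
      path = c(f$path, paste0(catalogue$label[[j]], "@CTERM")),
      has_cterm = FALSE, side_used = f$side_used)
    out[[length(out) + 1L]] <- child
    for (k in paired) {
      for (i in seq_along(f$codes)) {
        if (f$side_used[[i]] || f$codes[[i]] != catalogue$residues[[k]]) next
        su <- child$side_used
        su[[i]] <- TRUE
        out[[length(out) + 1L]] <- new_fragment(
          codes = child$codes, labels = child$labels,
          composition = comp_subtract(child$composition,
                                      catalogue$payload[[k]]),
          path = c(child$path,
                   paste0(catalogue$label[[k]], "@", f$labels[[i]])),
          has_cterm = FALSE, side_used = su)
      }
    }
  }
  out
}

#' Side-chain fragmentation events
#'
#' Emits one child per (open residue position, applicable side-chain event).
#' A relative event subtracts its payload from the parent and consumes that
#' position's single side-event slot; further events at other positions can
#' still apply to the child. A charged (non-relative) event emits a terminal
#' fragment whose composition *is* the payload ion -- its m/z is independent
#' of the parent, and it seeds no further fragmentation.
#'
#' @inheritParams apply_cterm_events
#' @return List of `pep_fragment`s (terminal charged fragments have an
#'   empty residue list).
#' @export
apply_side_events <- function(f, catalogue = builtin_catalogue()) {
  side <- which(catalogue$scope == "side")
  out <- list()
  for (i in seq_along(f$codes)) {
    if (f$side_used[[i]]) next
    for (j in side[catalogue$residues[side] == f$codes[[i]]]) {
      lab <- paste0(catalogue$label[[j]], "@", f$labels[[i]])
      if (catalogue$kind[[j]] == "relative") {
        su <- f$side_used
        su[[i]] <- TRUE
        out[[length(out) + 1L]] <- new_fragment(
          codes = f$codes, labels = f$labels,
          composition = comp_subtract(f$composition,
                                      catalogue$payload[[j]]),
          path = c(f$path, lab), has_cterm = f$has_cterm, side_used = su)
      } else {
        out[[length(out) + 1L]] <- new_fragment(
          codes = character(0), labels = character(0),
          composition = catalogue$payload[[j]],
          path = c(f$path, lab), has_cterm = FALSE,
          side_used = logical(0))
      }
    }
  }
  out
}

comp_key <- function(comp) paste(unclass(comp), collapse = ",")

#' Exhaustive combinatorial fragment enumeration
#'
#' Generates the full predicted m/z fingerprint of a peptide:
#'
#' 1. assemble the intact molecular ion;
#' 2. apply every Type A, then Type B, then Type C backbone cut to the
#'    intact peptide, keeping both complementary pieces (pieces containing
#'    no residue, such as a bare carboxyl radical, are dropped -- a fragment
#'    is modeled as a residue chain);
#' 3. apply the three C-terminal degradations (with alkene pairing for
#'    Lys/Pro/Ile) to the intact peptide;
#' 4. subject every pooled fragment, and recursively every child, to all
#'    applicable side-chain events, at most one per residue position;
#' 5. drop fragments with any negative atom count and collapse duplicates
#'    at the elemental-formula level, keeping the first-generated mechanism
#'    path as the representative and counting the collapsed routes.
#'
#' Backbone cleavage is applied to the original peptide only; side-chain
#' events recurse. The process is deterministic: identical sequence and
#' catalogue always give identical output.
#'
#' @param sequence One-letter residue codes, N-terminus first.
#' @param catalogue A `mech_catalogue`.
#' @return A `prediction_set`: list with `sequence`, `fragments` (list of
#'   `pep_fragment`s, ordered by m/z then path), `mz` (sorted predicted
#'   m/z values) and `provenance`.
#' @examples
#' ps <- enumerate_fragments("QFA")
#' length(ps$fragments)   # 55, including the intact molecular ion
#' @export
enumerate_fragments <- function(sequence, catalogue = builtin_catalogue()) {
  m <- assemble_peptide(sequence)
  pool <- c(list(m),
            cleave_type_a(m), cleave_type_b(m), cleave_type_c(m),
            apply_cterm_events(m, catalogue))
  pool <- Filter(function(f) length(f$codes) > 0L || length(f$path) == 0L,
                 pool)
  # breadth-first side-event recursion over the pool
  queue <- pool
  head <- 1L
  emitted <- list()
  while (head <= length(queue)) {
    f <- queue[[head]]
    head <- head + 1L
    emitted[[length(emitted) + 1L]] <- f
    children <- apply_side_events(f, catalogue)
    for (ch in children) {
      if (length(ch$codes) > 0L) {
        queue[[length(queue) + 1L]] <- ch
      } else {
        emitted[[length(emitted) + 1L]] <- ch   # terminal charged ion
      }
    }
  }
  frags <- dedupe_and_filter(emitted)
  new_prediction_set(sequence, frags, catalogue_provenance(catalogue))
}

#' Duplicate removal and negative-mass filtering
#'
#' Removes fragments with any negative atom count (overlapping predicted
#' losses) and collapses duplicates at the elemental-formula level: the
#' first fragment generated with a given composition is kept as the
#' representative and the number of distinct generation routes that reached
#' that formula is recorded in its `n_routes` field. Output ordering is
#' stable: ascending m/z, then path text. Idempotent.
#'
#' @param fragments List of `pep_fragment`s.
#' @return Filtered, deduplicated, ordered list of `pep_fragment`s.
#' @export
dedupe_and_filter <- function(fragments) {
  seen <- new.env(parent = emptyenv())
  kept <- list()
  for (f in fragments) {
    if (any(unclass(f$composition)[1:5] < 0L)) next
    key <- comp_key(f$composition)
    hit <- seen[[key]]
    if (is.null(hit)) {
      f$n_routes <- (f$n_routes %||% 1L)
      kept[[length(kept) + 1L]] <- f
      seen[[key]] <- length(kept)
    } else {
      kept[[hit]]$n_routes <- kept[[hit]]$n_routes + (f$n_routes %||% 1L)
    }
  }
  if (length(kept) == 0L) return(kept)
  mz <- vapply(kept, function(f) monoisotopic_mass(f$composition), 0)
  ptxt <- vapply(kept, function(f) paste(f$path, collapse = " > "), "")
  kept[order(mz, ptxt)]
}

new_prediction_set <- function(sequence, fragments, provenance) {
  structure(list(sequence = sequence, fragments = fragments,
                 mz = vapply(fragments,
                             function(f) monoisotopic_mass(f$composition),
                             0),
                 provenance = provenance),
            class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("<prediction_set %s: %d fragments, m/z %.2f-%.2f (%s)>\n",
              x$sequence, length(x$fragments),
              min(x$mz), max(x$mz), x$provenance))
  invisible(x)
}

#' @export
as.data.frame.prediction_set <- function(x, ...) {
  data.frame(
    mz = round(x$mz, 4),
    composition = vapply(x$fragments,
                         function(f) format_composition(f$composition), ""),
    path = vapply(x$fragments, function(f) {
      if (length(f$path)) paste(f$path, collapse = " > ") else "intact"
    }, ""),
    n_routes = vapply(x$fragments, function(f) f$n_routes %||% 1L, 0L),
    stringsAsFactors = FALSE)
}

#' Write a prediction set as tab-separated text
#'
#' One fragment per row: m/z at four decimals, elemental composition,
#' mechanism path, and the number of generation routes collapsed into the
#' row. Two comment lines record the source sequence and the catalogue
#' provenance.
#'
#' @param predictions A `prediction_set`.
#' @param path Output file path.
#' @export
write_predictions <- function(predictions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# sequence: ", predictions$sequence),
               paste0("# catalogue: ", predictions$provenance)), con)
  df <- as.data.frame(predictions)
  df$mz <- sprintf("%.4f", df$mz)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
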