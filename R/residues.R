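#' The residue table
#'
#' Free-molecule elemental compositions, side-chain classes and derived
#' side-chain compositions for the 20 proteinogenic amino acids. The table
#' ships as a plain-text data file (`extdata/residues.txt`) so nonstandard
#' residues can be supplied by pointing `path` at a user file with the same
#' layout: `code | name | class | C,H,N,O,S`.
#'
#' The side-chain composition of each residue is the free molecule minus the
#' invariant backbone remainder C2H4NO2; for glycine this leaves a single
#' hydrogen.
#'
#' @param path Optional path to an alternative residue definition file.
#' @return A data frame with one row per residue: `code`, `name`, `class`,
#'   and list-columns `free` and `side_chain` of `el_comp` objects.
#' @examples
#' rt <- residue_table()
#' rt[rt$code == "G", "side_chain"][[1]]
#' @export
residue_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.eifrag_cache$residues)) return(.eifrag_cache$residues)
    path <- system.file("extdata", "residues.txt", package = "eifrag",
                        mustWork = TRUE)
    builtin <- TRUE
  } else {
    builtin <- FALSE
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  recs <- strsplit(trimws(lines[keep]), "\\s*\\|\\s*")
  bad <- which(lengths(recs) != 4L)
  if (length(bad)) {
    stop("malformed residue record on line ", which(keep)[bad[1L]],
         " of ", path, call. = FALSE)
  }
  code  <- vapply(recs, `[[`, "", 1L)
  name  <- vapply(recs, `[[`, "", 2L)
  class <- vapply(recs, `[[`, "", 3L)
  free <- lapply(recs, function(r) {
    v <- suppressWarnings(as.numeric(strsplit(r[[4L]], ",")[[1L]]))
    if (length(v) != 5L || anyNA(v)) {
      stop("malformed formula field in residue record: ", r[[4L]],
           call. = FALSE)
    }
    composition(v[1L], v[2L], v[3L], v[4L], v[5L])
  })
  if (anyDuplicated(code)) {
    stop("duplicate residue code in ", path, call. = FALSE)
  }
  side <- lapply(free, comp_subtract, BACKBONE_REMAINDER)
  out <- data.frame(code = code, name = name, class = class,
                    stringsAsFactors = FALSE)
  out$free <- free
  out$side_chain <- side
  if (builtin) .eifrag_cache$residues <- out
  out
}

.eifrag_cache <- new.env(parent = emptyenv())

residue_lookup <- function(codes, table = residue_table()) {
  idx <- match(codes, table$code)
  if (anyNA(idx)) {
    stop("unknown residue code: ",
         paste(unique(codes[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  idx
}

#' Validate and split a peptide sequence
#'
#' @param sequence Character scalar of one-letter residue codes; the first
#'   character is the N-terminus.
#' @return Character vector of single codes.
#' @keywords internal
split_sequence <- function(sequence, table = residue_table()) {
  if (!is.character(sequence) || length(sequence) != 1L ||
      is.na(sequence) || !nzchar(sequence)) {
    stop("sequence must be a single non-empty character string",
         call. = FALSE)
  }
  codes <- strsplit(sequence, "")[[1L]]
  residue_lookup(codes, table)   # errors on unknown codes
  codes
}

#' Assemble a peptide from its sequence
#'
#' Sums the free-molecule compositions of the residues and removes one water
#' per peptide bond, the condensation bookkeeping applied when the fragment
#' object is initialized. The result is the intact molecular ion M+.: in EI
#' positive-ion mode the radical cation's m/z equals the neutral
#' monoisotopic mass (charge is flagged +1; no proton is added and the
#' electron mass is neglected).
#'
#' @param sequence One-letter codes, N-terminus first.
#' @param table Residue table (see [residue_table()]).
#' @return A `pep_fragment`: the intact peptide with an empty mechanism
#'   path, position labels like `"Q1"`, and `has_cterm = TRUE`.
#' @examples
#' p <- assemble_peptide("QFA")
#' round(monoisotopic_mass(p$composition), 2)   # 364.17
#' @export
assemble_peptide <- function(sequence, table = residue_table()) {
  codes <- split_sequence(sequence, table)
  idx <- residue_lookup(codes, table)
  comp <- composition(charge = 1L)
  for (i in idx) comp <- comp_add(comp, table$free[[i]])
  n <- length(codes)
  if (n > 1L) {
    comp <- comp_subtract(comp, composition(h_count = 2L * (n - 1L),
                                            o_count = n - 1L))
  }
  new_fragment(
    codes = codes,
    labels = paste0(codes, seq_len(n)),
    composition = comp,
    path = character(0),
    has_cterm = TRUE,
    side_used = rep.int(FALSE, n)
  )
}
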