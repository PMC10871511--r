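# Independent brute-force enumerator for single free amino acids.
#
# Works directly from the published event tables as hand-coded payload
# vectors (C,H,N,O,S) -- deliberately sharing no code with the engine or
# the catalogue -- and enumerates every legal event subset in closed form:
# a single residue has one side-event slot, backbone cleavage applies only
# to the original species, and C-terminal degradations apply once.

oracle_key <- function(v) paste(v[1:5], collapse = ",")

oracle_side_payloads <- function(code, free) {
  p <- list()
  add <- function(v) p[[length(p) + 1L]] <<- v
  if (code %in% c("N", "Q")) add(c(0, 3, 1, 0, 0))
  if (code %in% c("S", "T")) add(c(0, 2, 0, 1, 0))
  if (code == "C") add(c(0, 2, 0, 0, 1))
  if (code %in% c("D", "E")) {
    add(c(1, 1, 0, 2, 0)); add(c(0, 1, 0, 1, 0)); add(c(0, 2, 0, 1, 0))
  }
  if (code == "M") add(c(2, 5, 0, 0, 1))
  if (code %in% strsplit("CDEFHIKLMNQRSTVW", "")[[1L]]) {
    add(free - c(2, 4, 1, 2, 0))
  }
  if (code == "K") add(c(0, 3, 1, 0, 0))
  if (code == "R") {
    add(c(1, 2, 2, 0, 0)); add(c(1, 6, 3, 0, 0))
  }
  p
}

oracle_charged_ions <- function(code) {
  switch(code,
         F = list(c(7, 7, 0, 0, 0), c(8, 7, 0, 0, 0)),
         Y = list(c(7, 7, 0, 1, 0), c(8, 7, 0, 1, 0)),
         W = list(c(9, 8, 1, 0, 0)),
         H = list(c(4, 5, 2, 0, 0), c(5, 5, 2, 0, 0), c(4, 6, 2, 0, 0)),
         M = list(c(3, 7, 0, 0, 1), c(2, 5, 0, 0, 1)),
         L = list(c(4, 9, 0, 0, 0)),
         list())
}

# returns the sorted set of unique non-negative atom-count vectors (as
# keys) predicted for one free amino acid
oracle_single_aa <- function(code) {
  rt <- residue_table()
  free <- unclass(rt$free[[match(code, rt$code)]])[1:5]
  co2h <- c(1, 1, 0, 2, 0); oh <- c(0, 1, 0, 1, 0); h2o <- c(0, 2, 0, 1, 0)

  # base species: (neutral composition, side-slot still open?)
  bases <- list(list(free, TRUE),            # molecular ion
                list(free - co2h, TRUE))     # Type A N-side piece
  if (code %in% c("F", "W", "Y")) {          # Type C C-side piece
    bases[[length(bases) + 1L]] <- list(free - c(0, 2, 1, 0, 0), TRUE)
  }
  for (loss in list(co2h, oh, h2o)) {        # C-terminal degradations
    bases[[length(bases) + 1L]] <- list(free - loss, TRUE)
    if (code %in% c("K", "P", "I")) {        # paired alkene, slot consumed
      bases[[length(bases) + 1L]] <- list(free - loss - c(0, 1, 0, 0, 0),
                                          FALSE)
    }
  }

  out <- character(0)
  side <- oracle_side_payloads(code, free)
  for (b in bases) {
    if (all(b[[1L]] >= 0)) out <- c(out, oracle_key(b[[1L]]))
    if (b[[2L]]) {
      for (pay in side) {
        v <- b[[1L]] - pay
        if (all(v >= 0)) out <- c(out, oracle_key(v))
      }
    }
  }
  for (ion in oracle_charged_ions(code)) out <- c(out, oracle_key(ion))
  sort(unique(out))
}

engine_keys <- function(ps) {
  sort(unique(vapply(ps$fragments,
                     function(f) oracle_key(unclass(f$composition)), "")))
}
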