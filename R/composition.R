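#' Elemental compositions
#'
#' Every species handled by the prediction model -- peptides, backbone
#' fragments, neutral losses, charged side-chain ions -- is described by a
#' six-component integer vector: the numbers of C, H, N, O and S atoms plus
#' the net charge in elementary units. Atom counts may go transiently
#' negative while fragmentation events are being stacked; emitted predictions
#' are filtered to non-negative counts (see [enumerate_fragments()]).
#'
#' @param c_count,h_count,n_count,o_count,s_count Integer atom counts.
#' @param charge Net charge in elementary units (positive-ion detection mode
#'   uses +1).
#' @return An object of class `el_comp`: a named integer vector with
#'   components `C`, `H`, `N`, `O`, `S`, `z`.
#' @examples
#' composition(3, 7, 1, 2)            # free alanine, neutral
#' composition(7, 7, charge = 1)      # tropylium-type side-chain ion
#' @export
composition <- function(c_count = 0L, h_count = 0L, n_count = 0L,
                        o_count = 0L, s_count = 0L, charge = 0L) {
  x <- c(C = c_count, H = h_count, N = n_count, O = o_count,
         S = s_count, z = charge)
  if (any(x != round(x))) {
    stop("composition components must be integers", call. = FALSE)
  }
  structure(as.integer(round(x)),
            names = c("C", "H", "N", "O", "S", "z"),
            class = "el_comp")
}

as_composition <- function(x) {
  if (inherits(x, "el_comp")) return(x)
  if (is.numeric(x) && length(x) == 6L) {
    return(composition(x[[1L]], x[[2L]], x[[3L]], x[[4L]], x[[5L]], x[[6L]]))
  }
  stop("cannot interpret object as an elemental composition", call. = FALSE)
}

#' @export
print.el_comp <- function(x, ...) {
  cat(format_composition(x), "\n")
  invisible(x)
}

#' Add or subtract elemental compositions
#'
#' Componentwise arithmetic over all six fields (atom counts and charge).
#' Subtraction may produce negative counts; callers filter such species
#' before emitting predictions.
#'
#' @param a,b `el_comp` objects (or length-6 numeric vectors).
#' @return An `el_comp`.
#' @examples
#' gly <- composition(2, 5, 1, 2)
#' comp_add(gly, gly)
#' comp_subtract(gly, composition(h_count = 2, o_count = 1))
#' @export
comp_add <- function(a, b) {
  a <- as_composition(a); b <- as_composition(b)
  structure(unclass(a) + unclass(b), class = "el_comp")
}

#' @rdname comp_add
#' @export
comp_subtract <- function(a, b) {
  a <- as_composition(a); b <- as_composition(b)
  structure(unclass(a) - unclass(b), class = "el_comp")
}

# monoisotopic atomic masses, Da
MONO_MASS <- c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
               O = 15.9949146221, S = 31.97207069)

#' Monoisotopic mass / m/z of a composition
#'
#' Sum of atom counts times monoisotopic atomic masses. For a singly charged
#' species the value is returned as the m/z directly; the electron mass
#' (0.00055 Da) is neglected, which is far inside the +/- 0.25 m/z matching
#' tolerance used throughout.
#'
#' @param x An `el_comp`.
#' @return Mass in Da (m/z for |charge| = 1).
#' @examples
#' monoisotopic_mass(composition(7, 7, charge = 1))   # 91.05, prints as 91.1
#' @export
monoisotopic_mass <- function(x) {
  x <- as_composition(x)
  if (abs(x[["z"]]) > 1L) {
    stop("only |charge| <= 1 supported: m/z division by multiple charges ",
         "is not implemented", call. = FALSE)
  }
  sum(unclass(x)[1:5] * MONO_MASS)
}

format_composition <- function(x) {
  x <- as_composition(x)
  el <- c("C", "H", "N", "O", "S")
  n <- unclass(x)[1:5]
  body <- paste0(el[n != 0L], n[n != 0L], collapse = "")
  if (body == "") body <- "(empty)"
  z <- x[["z"]]
  zs <- if (z == 0L) "" else if (z == 1L) "+" else if (z == -1L) "-" else
    sprintf("%+d", z)
  paste0(body, zs)
}

WATER   <- composition(h_count = 2L, o_count = 1L)
CO2H    <- composition(c_count = 1L, h_count = 1L, o_count = 2L)
HYDROXYL<- composition(h_count = 1L, o_count = 1L)
AMMONIA <- composition(h_count = 3L, n_count = 1L)
H_ATOM  <- composition(h_count = 1L)
# backbone remainder left after removing the side chain from a free amino
# acid: H2N-CH-COOH less the alpha hydrogen's substituent, i.e. C2H4NO2
BACKBONE_REMAINDER <- composition(2L, 4L, 1L, 2L)
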