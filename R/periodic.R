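# Static periodic-table data for the supported element set.
# Covalent radii: Cordero et al. single-bond values (Angstrom).
# Electronegativity: Pauling scale; hardness: Pearson absolute hardness (eV),
# both used only by the surrogate charge scheme.
# Valence occupations are the neutral ground-state valence-shell (s, p, d)
# electron counts; d is zero across the supported set.
.ptable <- data.frame(
  symbol  = c("H", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I"),
  z       = c(1L, 6L, 7L, 8L, 9L, 15L, 16L, 17L, 35L, 53L),
  group   = c(1L, 14L, 15L, 16L, 17L, 15L, 16L, 17L, 17L, 17L),
  period  = c(1L, 2L, 2L, 2L, 2L, 3L, 3L, 3L, 4L, 5L),
  rcov    = c(0.31, 0.76, 0.71, 0.66, 0.57, 1.07, 1.05, 1.02, 1.20, 1.39),
  chi     = c(2.20, 2.55, 3.04, 3.44, 3.98, 2.19, 2.58, 3.16, 2.96, 2.66),
  eta     = c(6.43, 5.00, 7.23, 6.08, 7.01, 4.88, 4.14, 4.68, 4.22, 3.69),
  val_s   = c(1, 2, 2, 2, 2, 2, 2, 2, 2, 2),
  val_p   = c(0, 2, 3, 4, 5, 3, 4, 5, 5, 5),
  val_d   = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
  stringsAsFactors = FALSE
)

# Wider symbol set accepted at the IO layer (validation only; electronic
# weights are restricted to .ptable$symbol).
.ioElements <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe")

#' Element symbols accepted by the IO layer
#' @return character vector of symbols
#' @export
knownElements <- function() .ioElements

#' Element symbols supported by the electronic-weight providers
#' @return character vector of symbols
#' @export
supportedElements <- function() .ptable$symbol

canonicalElement <- function(sym) {
  sym <- trimws(sym)
  paste0(toupper(substr(sym, 1, 1)), tolower(substr(sym, 2, nchar(sym))))
}

ptableLookup <- function(symbols, what = "use") {
  idx <- match(symbols, .ptable$symbol)
  if (anyNA(idx)) {
    bad <- unique(symbols[is.na(idx)])
    stop("element(s) not supported by the electronic-weight providers (",
         what, "): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  .ptable[idx, , drop = FALSE]
}
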