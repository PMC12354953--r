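# Categorical feature vocabularies shared by the featurizer and the encoder.
# Indices are 1-based throughout.

# Atomic-number vocabulary: index = atomic number for Z in 1..118, plus a
# final out-of-range bucket.
ATOM_VOCAB_SIZE <- 119L

CHIRALITY_LEVELS <- c("unspecified", "tetrahedral_cw", "tetrahedral_ccw", "other")
BOND_TYPE_LEVELS <- c("single", "double", "triple", "aromatic")
BOND_DIR_LEVELS  <- c("none", "end_up_right", "end_down_right")

# index of the aromatic bond-type code; must never survive standardization
AROMATIC_BOND <- 4L

ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th",
  "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf", "Es", "Fm",
  "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og"
)

#' Map element symbols to atom-vocabulary indices
#'
#' The atom vocabulary indexes atoms by atomic number (1--118) with a final
#' out-of-vocabulary bucket at index 119 for unrecognized symbols.
#'
#' @param symbol character vector of element symbols (e.g. `"C"`, `"Cl"`).
#' @return integer vector of vocabulary indices.
#' @keywords internal
element_to_index <- function(symbol) {
  idx <- match(symbol, ELEMENT_SYMBOLS)
  idx[is.na(idx)] <- ATOM_VOCAB_SIZE
  as.integer(idx)
}
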