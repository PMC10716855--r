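# Physical constants and lookup tables shared across modules.

AVOGADRO <- 6.02214076e23

# standard atomic masses, Da
.ATOMIC_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  NA. = 22.990, CL = 35.45, P = 30.974, K = 39.098, MG = 24.305
)

#' Look up standard atomic masses
#'
#' @param element character vector of element symbols (case-insensitive;
#'   sodium may be given as "Na" or "NA").
#' @return numeric vector of masses in Da.
#' @keywords internal
atomic_mass <- function(element) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  m <- .ATOMIC_MASS[key]
  if (anyNA(m)) {
    stop("unknown element(s): ", paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

# average residue (monomer) masses, Da, for the 20 standard amino acids
.RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

.AA_THREE <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", E = "GLU",
  Q = "GLN", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)
.AA_ONE <- structure(names(.AA_THREE), names = unname(.AA_THREE))

#' Convert between one- and three-letter amino-acid codes
#' @param x character vector of codes.
#' @return character vector of the other representation.
#' @keywords internal
aa_three <- function(x) {
  out <- .AA_THREE[toupper(x)]
  if (anyNA(out)) stop("unknown amino-acid letter(s): ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  unname(out)
}

#' @rdname aa_three
#' @keywords internal
aa_one <- function(x) {
  out <- .AA_ONE[toupper(x)]
  if (anyNA(out)) stop("unknown residue name(s): ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  unname(out)
}

#' The reconstructed AQ3 spidroin sequence
#'
#' One-letter sequence of the simulated AQ3 construct: three tandem copies of
#' the engineered ADF3 dragline consensus repeat (an alanine-rich "A" module
#' followed by a glutamine/glycine-rich "Q" module).  The alanine-rich,
#' helix-forming stretches fall at residue indices 7-14, 51-58 and 95-102.
#' This is a reconstruction from the published repeat architecture, not a
#' deposited sequence; every function that needs a sequence accepts it as an
#' argument, with this constant as the convenience default.
#'
#' @format A length-one character string (132 residues).
#' @export
AQ3_SEQUENCE <- paste0(
  rep(paste0("GPYGPGASAAAAAAGGYGPGSGQQ",
             strrep("GPGQQ", 4)), 3L),
  collapse = ""
)

# default residue-name -> species mapping used by the structure readers
.DEFAULT_SPECIES_MAP <- c(
  SOL = "WATER", HOH = "WATER", TIP4 = "WATER", TIP3 = "WATER", WAT = "WATER",
  ETH = "ETHANOL", EOH = "ETHANOL", ETO = "ETHANOL",
  "NA" = "ION", CL = "ION", K = "ION", MG = "ION"
)

.SPECIES_LEVELS <- c("PROTEIN", "WATER", "ETHANOL", "ION")
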