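# Peptide construct modelling: average mass and formal charge of synthesized
# constructs (C-terminal amidation, disulfide bonds, N-terminal adducts).

# Average residue masses (Da) of the 20 standard amino acids as incorporated in
# a chain (monomer minus water), standard IUPAC average atomic weights.
.residue_mass <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

.mass_water     <- 18.0153
.mass_amidation <- -0.9847   # C-terminal -OH -> -NH2
.mass_disulfide <- -2.0159   # loss of 2 H per S-S bond

# N-terminal adduct registry: average mass of the free adduct molecule.
# Each adduct condenses onto the growing N-terminus through one amide bond,
# releasing one water; beta-alanine behaves as an extra (non-core) residue.
.adduct_mass <- c(
  beta_alanine = 89.0932,   # C3H7NO2
  biotinyl     = 244.3106,  # biotin C10H16N2O3S (acyl via its valeric acid)
  acetyl       = 60.0520,   # acetic acid C2H4O2
  dota         = 404.4155   # C16H28N4O8, mono-amide linkage via one acetate arm
)

#' Define a synthesized peptide construct
#'
#' A construct is a core sequence of standard residues plus the covalent
#' modifications common in synthetic amyloid peptides: C-terminal amidation,
#' intramolecular disulfide bonds, and an ordered list of N-terminal adducts
#' (listed outward from the core, e.g. \code{c("beta_alanine", "beta_alanine",
#' "biotinyl")} for a biotinyl-[beta-Ala]-[beta-Ala]- extension).
#'
#' @param sequence one-letter amino-acid string (20 standard residues).
#' @param c_term \code{"free_acid"} or \code{"amide"}.
#' @param n_term_adducts character vector of adduct names from the registry
#'   (\code{beta_alanine}, \code{biotinyl}, \code{dota}, \code{acetyl}),
#'   ordered from the core outward.
#' @param disulfides list of length-2 integer vectors, 1-based residue indices
#'   on the core sequence; both partners must be cysteines.
#' @return an object of class \code{peptide_construct}.
#' @examples
#' iapp <- peptide_construct(iapp_sequence(), c_term = "amide",
#'                           disulfides = list(c(2, 7)))
#' average_mass(iapp)
#' net_charge(iapp)
#' @export
peptide_construct <- function(sequence, c_term = c("free_acid", "amide"),
                              n_term_adducts = character(),
                              disulfides = list()) {
  c_term <- match.arg(c_term)
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  sequence <- gsub("[[:space:]]", "", sequence)
  letters1 <- strsplit(sequence, "")[[1]]
  bad <- which(!letters1 %in% names(.residue_mass))
  if (length(bad))
    stop("unknown residue letter '", letters1[bad[1]], "' at position ", bad[1])
  if (length(n_term_adducts)) {
    unknown <- setdiff(n_term_adducts, names(.adduct_mass))
    if (length(unknown))
      stop("unknown adduct(s): ", paste(unknown, collapse = ", "))
  }
  for (ss in disulfides) {
    if (length(ss) != 2L || anyNA(ss))
      stop("each disulfide must be a pair of residue indices")
    if (any(ss < 1L) || any(ss > length(letters1)))
      stop("disulfide index out of range: ", paste(ss, collapse = "-"))
    if (any(letters1[ss] != "C"))
      stop("disulfide partners must be cysteines (got ",
           paste(letters1[ss], collapse = ", "), " at ",
           paste(ss, collapse = "-"), ")")
  }
  structure(
    list(sequence = sequence, residues = letters1, c_term = c_term,
         n_term_adducts = as.character(n_term_adducts),
         disulfides = disulfides),
    class = "peptide_construct")
}

#' Human IAPP (amylin) one-letter sequence
#'
#' The 37-residue sequence of human islet amyloid polypeptide.
#' @return character scalar.
#' @export
iapp_sequence <- function() "KCNTATCATQRLANFLVHSSNNFGAILSSTNVGSNTY"

#' @export
print.peptide_construct <- function(x, ...) {
  cat("Peptide construct:", length(x$residues), "residues\n")
  cat("  sequence:", x$sequence, "\n")
  cat("  C-terminus:", x$c_term, "\n")
  if (length(x$n_term_adducts))
    cat("  N-terminal adducts:", paste(x$n_term_adducts, collapse = "-"), "\n")
  if (length(x$disulfides))
    cat("  disulfides:",
        paste(vapply(x$disulfides, paste, "", collapse = "-"), collapse = ", "),
        "\n")
  cat("  average mass:", format(average_mass(x), nsmall = 1), "Da\n")
  invisible(x)
}

#' Average molecular mass of a peptide construct
#'
#' Sum of standard average residue masses plus one water, corrected for
#' C-terminal amidation (-0.985 Da), disulfide bonds (-2.016 Da each), and
#' N-terminal adducts (adduct average mass minus one water per amide bond
#' formed). Reported rounded to 0.1 Da.
#'
#' @param p a \code{peptide_construct}.
#' @param digits decimal digits for rounding (default 1).
#' @return mass in Da.
#' @export
average_mass <- function(p, digits = 1) {
  stopifnot(inherits(p, "peptide_construct"))
  m <- sum(.residue_mass[p$residues]) + .mass_water
  if (p$c_term == "amide") m <- m + .mass_amidation
  m <- m + length(p$disulfides) * .mass_disulfide
  for (a in p$n_term_adducts) m <- m + .adduct_mass[[a]] - .mass_water
  round(unname(m), digits)
}

#' Formal net charge of a peptide construct
#'
#' Under the default \code{"side_chain"} convention (neutral pH, histidine
#' neutral): Arg/Lys contribute +1, Asp/Glu -1, termini 0. The
#' \code{"full"} convention adds +1 for a free (unmodified) N-terminus and -1
#' for a free-acid C-terminus.
#'
#' @param p a \code{peptide_construct}.
#' @param convention \code{"side_chain"} (default) or \code{"full"}.
#' @return integer charge.
#' @export
net_charge <- function(p, convention = c("side_chain", "full")) {
  stopifnot(inherits(p, "peptide_construct"))
  convention <- match.arg(convention)
  q <- sum(p$residues %in% c("K", "R")) - sum(p$residues %in% c("D", "E"))
  if (convention == "full") {
    if (length(p$n_term_adducts) == 0L) q <- q + 1L
    if (p$c_term == "free_acid") q <- q - 1L
  }
  as.integer(q)
}

#' Core sequence length of a construct
#'
#' Number of residues in the core sequence; N-terminal adducts (including
#' beta-alanine spacers) are excluded by contract.
#'
#' @param p a \code{peptide_construct}.
#' @return integer.
#' @export
sequence_length <- function(p) {
  stopifnot(inherits(p, "peptide_construct"))
  length(p$residues)
}
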