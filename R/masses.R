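# Amino-acid mass tables and peptide/protein mass arithmetic.
#
# Residue masses are the mass of the amino-acid residue as incorporated in a
# peptide chain (free amino acid minus one water). A chain of n residues
# therefore weighs sum(residues) + one water. All values in Daltons.

#' @keywords internal
.AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' @keywords internal
.AA_AVG <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

.WATER_MONO <- 18.010565
.WATER_AVG <- 18.01528
.PROTON <- 1.007276

# Modification delta masses (monoisotopic).
.MOD_MASS <- c(
  carbamidomethyl = 57.02146, # iodoacetamide alkylation of Cys
  oxidation = 15.99491        # e.g. Met oxidation
)

.AA_LETTERS <- names(.AA_MONO)

#' Molecular mass of a protein or peptide sequence
#'
#' Sums residue masses and adds one water. Average mass is the convention for
#' protein-level reporting (molecular-mass distributions); monoisotopic mass
#' is used for peptide precursor m/z.
#'
#' @param sequence Character vector of amino-acid sequences (uppercase,
#'   standard 20-letter alphabet).
#' @param scale `"average"` (default) or `"monoisotopic"`.
#' @return Numeric vector of masses in Daltons.
#' @examples
#' protein_mass("G", scale = "monoisotopic") # 75.03203
#' protein_mass("AAAAAAK", scale = "monoisotopic")
#' @export
protein_mass <- function(sequence, scale = c("average", "monoisotopic")) {
  scale <- match.arg(scale)
  if (length(sequence) == 0L) return(numeric(0))
  if (any(is.na(sequence) | !nzchar(sequence)))
    pp_stop_input("protein_mass: empty sequence")
  check_sequence_alphabet(sequence)
  tab <- if (scale == "average") .AA_AVG else .AA_MONO
  water <- if (scale == "average") .WATER_AVG else .WATER_MONO
  vapply(sequence, function(s) {
    sum(tab[strsplit(s, "", fixed = TRUE)[[1L]]]) + water
  }, numeric(1), USE.NAMES = FALSE)
}

#' Monoisotopic peptide mass with modifications
#'
#' @param sequence Character vector of peptide sequences.
#' @param fixed_mods Character vector of fixed modifications applied wherever
#'   their residue occurs; supported: `"carbamidomethyl"` (every Cys,
#'   +57.02146 Da). Default applies carbamidomethylation, matching standard
#'   iodoacetamide sample preparation.
#' @param n_oxidation Integer vector: number of oxidized Met per peptide
#'   (+15.99491 Da each). Must not exceed the Met count of the peptide.
#' @return Numeric vector of monoisotopic masses in Daltons.
#' @export
peptide_mass <- function(sequence, fixed_mods = "carbamidomethyl",
                         n_oxidation = 0L) {
  base <- protein_mass(sequence, scale = "monoisotopic")
  n_oxidation <- rep_len(as.integer(n_oxidation), length(sequence))
  if (!all(fixed_mods %in% names(.MOD_MASS)))
    pp_stop_input(sprintf("unknown fixed modification: %s",
                          paste(setdiff(fixed_mods, names(.MOD_MASS)), collapse = ", ")))
  if ("carbamidomethyl" %in% fixed_mods)
    base <- base + stringi::stri_count_fixed(sequence, "C") * .MOD_MASS[["carbamidomethyl"]]
  n_met <- stringi::stri_count_fixed(sequence, "M")
  if (any(n_oxidation < 0L)) pp_stop_input("n_oxidation must be >= 0")
  if (any(n_oxidation > n_met))
    pp_stop_input("variable modification on absent residue: more oxidations than Met in peptide")
  base + n_oxidation * .MOD_MASS[["oxidation"]]
}

#' Precursor m/z of a peptide
#'
#' m/z = (monoisotopic mass + modification deltas + charge x proton) / charge,
#' with proton mass 1.007276 Da.
#'
#' @inheritParams peptide_mass
#' @param charge Integer charge state(s), 1..6.
#' @return Numeric vector of m/z values (Thomson).
#' @examples
#' peptide_mz("AAAAAAK", charge = 2, fixed_mods = character()) # 287.17137
#' @export
peptide_mz <- function(sequence, charge, fixed_mods = "carbamidomethyl",
                       n_oxidation = 0L) {
  charge <- as.integer(charge)
  if (any(is.na(charge)) || any(charge < 1L) || any(charge > 6L))
    pp_stop_input("charge must be an integer between 1 and 6")
  m <- peptide_mass(sequence, fixed_mods = fixed_mods, n_oxidation = n_oxidation)
  (m + charge * .PROTON) / charge
}

# Validate that sequences use only the 20 standard amino-acid letters.
# Returns invisibly; signals an input error naming the offending characters.
check_sequence_alphabet <- function(sequence, context = "sequence") {
  bad <- stringi::stri_detect_regex(sequence, "[^GASPVTCLINDQKEMHFRYW]")
  if (any(bad)) {
    chars <- unique(unlist(stringi::stri_extract_all_regex(
      sequence[bad], "[^GASPVTCLINDQKEMHFRYW]")))
    pp_stop_input(sprintf(
      "%s contains non-standard residue(s): %s (B/J/O/U/X/Z and other codes are rejected)",
      context, paste(chars, collapse = ", ")))
  }
  invisible(TRUE)
}
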