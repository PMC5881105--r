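# Fixed alphabets, descriptor group tables and physical constants used by the
# encoders. Feature name schemes are frozen here: FIS tables and model bundles
# are only portable across versions that agree on these names.

#' The 20-letter canonical amino acid alphabet, alphabetically ordered
#' @keywords internal
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# 400 ordered dipeptides in lexicographic order AA, AC, ..., YY
DIPEPTIDES <- paste0(rep(AA_ALPHABET, each = 20L), rep(AA_ALPHABET, 20L))

# Average (not monoisotopic) residue masses in Daltons; one water (18.015 Da)
# is added per chain when computing peptide molecular weight.
RESIDUE_MASS <- c(
  A = 71.0788, C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G = 57.0519, H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P = 97.1167, Q = 128.1307, R = 156.1875,
  S = 87.0782, T = 101.1051, V = 99.1326, W = 186.2132, Y = 163.1760)
WATER_MASS <- 18.015

# Residue classes for the physicochemical (PCP) descriptor block.
PCP_GROUPS <- list(
  hydrophobic = c("F", "I", "W", "L", "V", "M", "Y", "C", "A"),
  hydrophilic = c("R", "K", "N", "D", "E", "P"),
  neutral     = c("T", "H", "G", "S", "Q"),
  positive    = c("K", "H", "R"),
  negative    = c("D", "E"),
  turn        = c("N", "G", "P", "S"))

PCP_FEATURE_NAMES <- c(
  "PCP_hydrophobic_fraction", "PCP_hydrophilic_fraction",
  "PCP_neutral_fraction", "PCP_positive_fraction", "PCP_negative_fraction",
  "PCP_turn_fraction", "PCP_abs_charge", "PCP_mol_weight",
  "PCP_aliphatic_index")

# Three-group residue partitions for the seven CTD attributes, after the
# canonical protein-folding-class descriptor tables propagated by
# PROFEAT/iFeature. Each partition covers the 20 residues exactly once;
# validity is asserted by the test suite.
CTD_SCHEMES <- list(
  hydrophobicity = list(
    g1 = c("R", "K", "E", "D", "Q", "N"),                      # polar
    g2 = c("G", "A", "S", "T", "P", "H", "Y"),                 # neutral
    g3 = c("C", "L", "V", "I", "M", "F", "W")),                # hydrophobic
  normwaals = list(                                            # van der Waals volume
    g1 = c("G", "A", "S", "C", "T", "P", "D"),                 # 0-2.78
    g2 = c("N", "V", "E", "Q", "I", "L"),                      # 2.95-4.0
    g3 = c("M", "H", "K", "F", "R", "Y", "W")),                # 4.03-8.08
  polarity = list(
    g1 = c("L", "I", "F", "W", "C", "M", "V", "Y"),            # 4.9-6.2
    g2 = c("P", "A", "T", "G", "S"),                           # 8.0-9.2
    g3 = c("H", "Q", "R", "K", "N", "E", "D")),                # 10.4-13.0
  polarizability = list(
    g1 = c("G", "A", "S", "D", "T"),                           # 0-0.108
    g2 = c("C", "P", "N", "V", "E", "Q", "I", "L"),            # 0.128-0.186
    g3 = c("K", "M", "H", "F", "R", "Y", "W")),                # 0.219-0.409
  charge = list(
    g1 = c("K", "R"),                                          # positive
    g2 = c("A", "N", "C", "Q", "G", "H", "I", "L",
           "M", "F", "P", "S", "T", "W", "Y", "V"),            # neutral
    g3 = c("D", "E")),                                         # negative
  secondarystruct = list(
    g1 = c("E", "A", "L", "M", "Q", "K", "R", "H"),            # helix
    g2 = c("V", "I", "Y", "C", "W", "F", "T"),                 # strand
    g3 = c("G", "N", "P", "S", "D")),                          # coil
  solventaccess = list(
    g1 = c("A", "L", "F", "C", "G", "I", "V", "W"),            # buried
    g2 = c("R", "K", "Q", "E", "N", "D"),                      # exposed
    g3 = c("M", "S", "P", "T", "H", "Y")))                     # intermediate

# The eight high-quality AAindex accessions averaged by the AAI encoder.
AAI_ACCESSIONS <- c("BLAM930101", "BIOV880101", "MAXF760101", "TSAJ990101",
                    "NAKH920108", "CEDJ970104", "LIFS790101", "MIYS990104")

# seqinr::aaindex stores residue values under three-letter names.
AA3_TO_1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
              Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
              Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
              Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")

.aipkitCache <- new.env(parent = emptyenv())

#' Averaged high-quality AAindex profile
#'
#' Loads the eight AAindex tables named in [AAI_ACCESSIONS] from the
#' `seqinr` `aaindex` dataset, min-max normalizes each over the 20 residues
#' so no single index dominates, and averages them into one 20-value profile
#' used by [encodeAAI()].
#'
#' @return Named numeric vector of length 20 (names = [AA_ALPHABET]),
#'   values in `[0, 1]`.
#' @export
#' @examples
#' aaiProfile()["L"]
aaiProfile <- function() {
  if (!is.null(.aipkitCache$aai_profile)) return(.aipkitCache$aai_profile)
  env <- new.env(parent = emptyenv())
  utils::data("aaindex", package = "seqinr", envir = env)
  aaindex <- get("aaindex", envir = env)
  missing <- setdiff(AAI_ACCESSIONS, names(aaindex))
  if (length(missing) > 0L)
    stop("AAindex table(s) not available: ", paste(missing, collapse = ", "))
  mat <- vapply(AAI_ACCESSIONS, function(acc) {
    v <- aaindex[[acc]]$I
    names(v) <- AA3_TO_1[names(v)]
    v <- v[AA_ALPHABET]
    if (anyNA(v)) stop("AAindex table ", acc, " is incomplete")
    (v - min(v)) / (max(v) - min(v))
  }, numeric(20L))
  profile <- rowMeans(mat)
  names(profile) <- AA_ALPHABET
  .aipkitCache$aai_profile <- profile
  profile
}

# Unit-match substitution matrix for identity alignments (match 1, mismatch 0).
identityMatrix <- function() {
  if (is.null(.aipkitCache$idmat)) {
    m <- diag(1, 20L)
    dimnames(m) <- list(AA_ALPHABET, AA_ALPHABET)
    .aipkitCache$idmat <- m
  }
  .aipkitCache$idmat
}
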