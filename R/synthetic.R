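# Seeded generator of labeled peptide datasets with controllable
# class-conditional compositional structure. It exists to exercise the
# pipeline end-to-end, not to model immunology.

#' Generator profile for synthetic peptide classes
#'
#' Defines two class-conditional residue sampling distributions, optional
#' planted dipeptides, a length range and an effect-size scalar. With
#' `effectSize = 0` both classes collapse onto the midpoint of the two
#' weight vectors and planted-dipeptide insertion is switched off (a pure
#' null); `effectSize = 1` uses the profile weights and insertion
#' probabilities as given.
#'
#' @param residueWeightsPos,residueWeightsNeg Named non-negative weight
#'   vectors over the 20 residues (normalized internally).
#' @param plantedDipeptides Optional data frame with columns `dipeptide`
#'   (2-letter string), `class` (0/1) and `prob` (insertion probability in
#'   `[0, 1]`).
#' @param lengthRange Integer `c(min, max)` peptide lengths, min >= 2.
#'   Defaults to 5-25, typical of T-cell assay epitopes.
#' @param effectSize Scalar in `[0, 1]` scaling the class divergence.
#' @return A list of class `generatorProfile`.
#' @export
makeProfile <- function(residueWeightsPos, residueWeightsNeg,
                        plantedDipeptides = NULL, lengthRange = c(5L, 25L),
                        effectSize = 1) {
  norm <- function(w) {
    if (is.null(names(w)) || !setequal(names(w), AA_ALPHABET))
      stop("residue weights must be named over the 20 canonical residues")
    w <- w[AA_ALPHABET]
    if (any(w < 0) || sum(w) <= 0)
      stop("residue weights must be non-negative and not all zero")
    w / sum(w)
  }
  if (!is.null(plantedDipeptides)) {
    stopifnot(all(c("dipeptide", "class", "prob") %in%
                  names(plantedDipeptides)))
    if (!all(nchar(plantedDipeptides$dipeptide) == 2L) ||
        !all(plantedDipeptides$dipeptide %in% DIPEPTIDES))
      stop("planted dipeptides must be canonical residue pairs")
    if (any(plantedDipeptides$prob < 0 | plantedDipeptides$prob > 1))
      stop("insertion probabilities must lie in [0, 1]")
  }
  lengthRange <- as.integer(lengthRange)
  if (length(lengthRange) != 2L || lengthRange[1L] < 2L ||
      lengthRange[1L] > lengthRange[2L])
    stop("lengthRange must be c(min, max) with min >= 2")
  structure(list(pos = norm(residueWeightsPos),
                 neg = norm(residueWeightsNeg),
                 planted = plantedDipeptides,
                 lengthRange = lengthRange,
                 effectSize = effectSize),
            class = "generatorProfile")
}

#' Named generator presets
#'
#' * `null`: identical residue weights for both classes, nothing planted.
#' * `figure1_weak` / `figure1_strong`: the positive class up-weights
#'   L, K and R twofold and the negative class up-weights D, G, V, Y and P
#'   twofold (the residues reported dominant in AIPs and non-AIPs
#'   respectively); five dipeptides from the reported positive top-10 list
#'   (LL, LK, SL, IK, KR) are planted into positives and five from the
#'   negative list (DV, KG, DD, EF, GD) into negatives. The weak preset
#'   halves the effect size and insertion probability (0.15 vs 0.3).
#'
#' @param name Preset name; with no argument, returns the catalogue.
#' @return A `generatorProfile` (or a named list of them).
#' @export
#' @examples
#' defaultProfiles("figure1_strong")$planted
defaultProfiles <- function(name = NULL) {
  uniform <- stats::setNames(rep(1, 20L), AA_ALPHABET)
  posW <- uniform; posW[c("L", "K", "R")] <- 2
  negW <- uniform; negW[c("D", "G", "V", "Y", "P")] <- 2
  planted <- function(prob) data.frame(
    dipeptide = c("LL", "LK", "SL", "IK", "KR",
                  "DV", "KG", "DD", "EF", "GD"),
    class = rep(c(1L, 0L), each = 5L),
    prob = prob, stringsAsFactors = FALSE)
  catalogue <- list(
    null = makeProfile(uniform, uniform, effectSize = 0),
    figure1_weak = makeProfile(posW, negW, planted(0.15), effectSize = 0.5),
    figure1_strong = makeProfile(posW, negW, planted(0.3), effectSize = 1))
  if (is.null(name)) return(catalogue)
  if (!name %in% names(catalogue))
    stop("unknown preset '", name, "'; available: ",
         paste(names(catalogue), collapse = ", "))
  catalogue[[name]]
}

#' Generate a labeled synthetic peptide dataset
#'
#' Peptide lengths are uniform on the profile's length range; residues are
#' drawn i.i.d. from the class-conditional weights (moved toward the
#' midpoint of the two classes by `1 - effectSize`); each planted
#' dipeptide is written over two adjacent positions at a uniformly random
#' site with probability `effectSize * prob` (overwriting, not inserting,
#' keeps the length distribution class-independent). Deterministic given
#' `seed`.
#'
#' @param nPos,nNeg Number of positive / negative peptides (>= 0).
#' @param profile A `generatorProfile` (see [makeProfile()],
#'   [defaultProfiles()]).
#' @param seed Integer seed.
#' @return A labeled [PeptideSet-class] with ids `pos_1..` / `neg_1..`.
#' @export
#' @examples
#' ps <- generatePeptides(5, 5, defaultProfiles("figure1_strong"), seed = 1)
#' peptideLabels(ps)
generatePeptides <- function(nPos, nNeg, profile = defaultProfiles("null"),
                             seed = 1L) {
  stopifnot(inherits(profile, "generatorProfile"), nPos >= 0, nNeg >= 0)
  if (nPos + nNeg == 0L) stop("generate at least one peptide")
  e <- profile$effectSize
  mid <- (profile$pos + profile$neg) / 2
  wPos <- mid + e * (profile$pos - mid)
  wNeg <- mid + e * (profile$neg - mid)
  set.seed(mixSeed(seed, 53L))
  gen <- function(n, w, cls, tag) {
    if (n == 0L) return(character(0))
    planted <- profile$planted
    if (!is.null(planted)) planted <- planted[planted$class == cls, ,
                                              drop = FALSE]
    vapply(seq_len(n), function(i) {
      L <- sample(seq.int(profile$lengthRange[1L], profile$lengthRange[2L]),
                  1L)
      chars <- sample(AA_ALPHABET, L, replace = TRUE, prob = w)
      if (!is.null(planted) && nrow(planted) > 0L) {
        for (pi in seq_len(nrow(planted))) {
          if (runif(1) < e * planted$prob[pi]) {
            at <- sample.int(L - 1L, 1L)
            dip <- strsplit(planted$dipeptide[pi], "")[[1]]
            chars[at] <- dip[1L]; chars[at + 1L] <- dip[2L]
          }
        }
      }
      paste(chars, collapse = "")
    }, character(1))
  }
  seqsPos <- gen(nPos, wPos, 1L, "pos")
  seqsNeg <- gen(nNeg, wNeg, 0L, "neg")
  PeptideSet(c(seqsPos, seqsNeg),
             ids = c(if (nPos > 0) paste0("pos_", seq_len(nPos)),
                     if (nNeg > 0) paste0("neg_", seq_len(nNeg))),
             labels = rep(c(1L, 0L), c(nPos, nNeg)))
}
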