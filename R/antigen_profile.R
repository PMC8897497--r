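#' @importFrom stats sd
NULL

#' Align peptides to a protein by ungapped identity
#'
#' A peptide aligns at an offset if at least `min_match` of its residues
#' equal the protein residues there (ungapped). Each unique peptide
#' contributes 1 to every position of its best-scoring span; if several
#' offsets tie for the best score, each tied span is counted once. With
#' `best_only = FALSE` every offset reaching `min_match` contributes.
#'
#' @param peptides character vector of peptides (any length >=
#'   `min_match`); duplicated entries count once.
#' @param protein amino-acid string.
#' @param min_match minimum identical positions (6).
#' @param best_only count only best-scoring offsets (default) or all
#'   offsets above threshold.
#' @return integer vector of per-position coverage counts, length
#'   `nchar(protein)`.
#' @export
align_peptides_to_protein <- function(peptides, protein, min_match = 6,
                                      best_only = TRUE) {
  peptides <- unique(peptides)
  n <- nchar(protein)
  cov <- integer(n)
  if (length(peptides) == 0L || n == 0L) return(cov)
  pc <- strsplit(protein, "", fixed = TRUE)[[1]]
  for (pep in peptides) {
    w <- nchar(pep)
    if (w > n) next
    ch <- strsplit(pep, "", fixed = TRUE)[[1]]
    offs <- seq_len(n - w + 1L)
    score <- integer(length(offs))
    for (i in seq_len(w))
      score <- score + (pc[offs + i - 1L] == ch[i])
    hit <- if (best_only) {
      if (max(score) < min_match) integer(0) else offs[score == max(score)]
    } else offs[score >= min_match]
    for (o in hit) cov[o:(o + w - 1L)] <- cov[o:(o + w - 1L)] + 1L
  }
  cov
}

#' Signal-to-random alignment profile along a target antigen
#'
#' The signal track counts unique subject peptides aligned (>=
#' `min_match` identities) per protein position; the random track does
#' the same for residue-scrambled versions of the same peptides (one
#' scramble per peptide, a composition-matched paired null). The
#' per-position ratio is (signal + eps) / (random + eps).
#'
#' @param peptides character vector of a subject's peptides.
#' @param protein target protein sequence.
#' @param seed integer seed for the scramble.
#' @param min_match minimum identical positions (6).
#' @param eps pseudocount for the ratio (1).
#' @param n_scrambles number of scrambles averaged for the random track
#'   (1 = paired null as in the original workflow).
#' @return data.frame of class `mva_profile`: `position` (1-based),
#'   `signal`, `random`, `ratio`.
#' @export
signal_to_random_profile <- function(peptides, protein, seed,
                                     min_match = 6, eps = 1,
                                     n_scrambles = 1) {
  if (missing(seed)) stop("seed is mandatory")
  signal <- align_peptides_to_protein(peptides, protein, min_match)
  random <- numeric(nchar(protein))
  if (length(peptides)) {
    for (i in seq_len(n_scrambles)) {
      scr <- scramble_peptides(peptides, seed = seed + i - 1L)
      random <- random + align_peptides_to_protein(scr, protein, min_match)
    }
    random <- random / n_scrambles
  }
  structure(
    data.frame(position = seq_len(nchar(protein)),
               signal = signal, random = random,
               ratio = (signal + eps) / (random + eps)),
    class = c("mva_profile", "data.frame"))
}

#' Per-subject abundance of epitope-containing peptides
#'
#' For each subject, the summed read count of peptides containing the
#' pattern. With a threshold (e.g. 1200 for the MVA+ seropositivity call
#' on P.DT.PR-containing peptides), a binary call is attached.
#'
#' @param cohort `mva_cohort`.
#' @param pattern pattern string or `mva_pattern`.
#' @param threshold optional abundance threshold; subjects strictly above
#'   it are called positive.
#' @return data.frame: `subject_id`, `abundance`, and `positive` when a
#'   threshold is supplied.
#' @export
epitope_containing_abundance <- function(cohort, pattern, threshold = NULL) {
  ab <- motif_abundance(list(pattern), cohort)
  out <- data.frame(subject_id = colnames(ab), abundance = as.numeric(ab[1L, ]),
                    stringsAsFactors = FALSE)
  if (!is.null(threshold)) out$positive <- out$abundance > threshold
  out
}
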