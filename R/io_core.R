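#' @importFrom utils read.delim write.table head
#' @importFrom stats cor.test
NULL

CAD_GROUPS   <- c("noCAD", "sCAD", "ACS")
PERIO_GROUPS <- c("H", "G", "P")
SMOKING_LEVELS <- c("never", "ex", "active")

#' Construct a cohort table
#'
#' The raw input of the pipeline: one row per (subject, peptide) with a
#' sequencing read count, plus per-subject clinical metadata.
#'
#' @param counts data.frame with columns `subject_id`, `peptide` (12-aa
#'   upper-case string), `count` (non-negative integer).
#' @param subjects data.frame with columns `subject_id`, `cad_group`
#'   (noCAD/sCAD/ACS), `perio_group` (H/G/P), `smoking` (never/ex/active),
#'   `diabetes` (logical), `age`, `sex` (F/M), `ebv_ca_seropositive`
#'   (logical).
#' @return object of class `mva_cohort`.
#' @export
new_cohort <- function(counts, subjects) {
  counts <- as.data.frame(counts)
  subjects <- as.data.frame(subjects)
  req_c <- c("subject_id", "peptide", "count")
  req_s <- c("subject_id", "cad_group", "perio_group", "smoking",
             "diabetes", "age", "sex", "ebv_ca_seropositive")
  if (!all(req_c %in% names(counts)))
    stop("counts must have columns: ", paste(req_c, collapse = ", "))
  if (!all(req_s %in% names(subjects)))
    stop("subjects must have columns: ", paste(req_s, collapse = ", "))
  counts$peptide <- toupper(as.character(counts$peptide))
  counts$subject_id <- as.character(counts$subject_id)
  subjects$subject_id <- as.character(subjects$subject_id)
  validate_cohort_frames(counts, subjects)
  counts$count <- as.integer(counts$count)
  subjects$age <- as.numeric(subjects$age)
  counts <- counts[order(counts$subject_id, counts$peptide), req_c]
  subjects <- subjects[order(subjects$subject_id), req_s]
  rownames(counts) <- NULL
  rownames(subjects) <- NULL
  structure(list(counts = counts, subjects = subjects), class = "mva_cohort")
}

validate_cohort_frames <- function(counts, subjects) {
  if (anyDuplicated(subjects$subject_id))
    stop("duplicate subject_id in metadata: ",
         paste(unique(subjects$subject_id[duplicated(subjects$subject_id)]), collapse = ", "))
  bad <- which(nchar(counts$peptide) != 12L)
  if (length(bad))
    stop("peptide of length != 12 at counts row ", bad[1L], ": '",
         counts$peptide[bad[1L]], "'")
  ok_alpha <- grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"),
                    counts$peptide)
  if (!all(ok_alpha))
    stop("peptide with non-standard residues at counts row ",
         which(!ok_alpha)[1L], ": '", counts$peptide[which(!ok_alpha)[1L]], "'")
  if (any(is.na(counts$count)) || any(counts$count < 0) ||
      any(counts$count != floor(counts$count)))
    stop("counts must be non-negative integers (first bad row ",
         which(is.na(counts$count) | counts$count < 0 |
               counts$count != floor(counts$count))[1L], ")")
  dup <- duplicated(counts[, c("subject_id", "peptide")])
  if (any(dup))
    stop("duplicate (subject, peptide) at counts row ", which(dup)[1L])
  unknown <- setdiff(unique(counts$subject_id), subjects$subject_id)
  if (length(unknown))
    stop("subjects in counts absent from metadata: ",
         paste(unknown, collapse = ", "))
  if (!all(subjects$cad_group %in% CAD_GROUPS))
    stop("cad_group must be one of ", paste(CAD_GROUPS, collapse = "/"))
  if (!all(subjects$perio_group %in% PERIO_GROUPS))
    stop("perio_group must be one of ", paste(PERIO_GROUPS, collapse = "/"))
  if (!all(subjects$smoking %in% SMOKING_LEVELS))
    stop("smoking must be one of ", paste(SMOKING_LEVELS, collapse = "/"))
  if (!all(subjects$sex %in% c("F", "M"))) stop("sex must be F or M")
  invisible(TRUE)
}

#' @export
print.mva_cohort <- function(x, ...) {
  cat("<mva_cohort> ", nrow(x$subjects), " subjects, ",
      nrow(x$counts), " (subject, peptide) count entries\n", sep = "")
  cat("  CAD groups:  ", paste(sprintf("%s=%d", CAD_GROUPS,
      vapply(CAD_GROUPS, function(g) sum(x$subjects$cad_group == g), 0L)),
      collapse = " "), "\n", sep = "")
  cat("  perio groups:", paste(sprintf("%s=%d", PERIO_GROUPS,
      vapply(PERIO_GROUPS, function(g) sum(x$subjects$perio_group == g), 0L)),
      collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Load a cohort from counts and metadata TSV files
#'
#' @param counts_path TSV with header `subject_id`, `peptide`, `count`.
#' @param metadata_path TSV with one row per subject (see [new_cohort()]).
#' @return `mva_cohort`. Lower-case peptides are upper-cased; malformed
#'   rows, peptides of length != 12, duplicate (subject, peptide) rows and
#'   subjects missing from the metadata all raise errors naming the row.
#' @export
load_cohort <- function(counts_path, metadata_path) {
  counts <- read.delim(counts_path, sep = "\t", header = TRUE,
                       colClasses = c(subject_id = "character",
                                      peptide = "character"),
                       stringsAsFactors = FALSE)
  meta <- read.delim(metadata_path, sep = "\t", header = TRUE,
                     colClasses = c(subject_id = "character",
                                    cad_group = "character",
                                    perio_group = "character",
                                    smoking = "character",
                                    sex = "character"),
                     stringsAsFactors = FALSE)
  if (any(is.na(counts$count)))
    stop("malformed count at counts row ", which(is.na(counts$count))[1L])
  meta$diabetes <- as.logical(meta$diabetes)
  meta$ebv_ca_seropositive <- as.logical(meta$ebv_ca_seropositive)
  new_cohort(counts, meta)
}

#' Write a cohort to canonical TSV files
#'
#' Rows are written in canonical order (subject then peptide), so that
#' load -> write -> load is the identity.
#'
#' @param cohort `mva_cohort`.
#' @param counts_path,metadata_path output TSV paths.
#' @return invisibly, the cohort.
#' @export
write_cohort <- function(cohort, counts_path, metadata_path) {
  stopifnot(inherits(cohort, "mva_cohort"))
  write.table(cohort$counts, counts_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$subjects, metadata_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(cohort)
}

#' Read a proteome from a FASTA file
#'
#' Accessions follow the UniProt convention: for headers of the form
#' `sp|Q7MTG1|NAME` or `tr|...|...` the middle token is the accession;
#' plain headers use the first whitespace-delimited token. Sequences with
#' residues outside the 20-letter alphabet are kept but flagged with a
#' warning.
#'
#' @param path FASTA file (multi-line sequences allowed).
#' @return named character vector of upper-case sequences, class
#'   `mva_proteome`.
#' @export
read_fasta_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("no sequences in FASTA file '", path, "'")
  headers <- names(aa)
  first_tok <- vapply(strsplit(headers, "[ \t]"), `[`, character(1), 1L)
  acc <- vapply(first_tok, function(tok) {
    parts <- strsplit(tok, "|", fixed = TRUE)[[1]]
    if (length(parts) == 3L && parts[1L] %in% c("sp", "tr")) parts[2L] else tok
  }, character(1), USE.NAMES = FALSE)
  if (anyDuplicated(acc))
    stop("duplicate accession in FASTA: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  seqs <- toupper(as.character(aa))
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for accession ", acc[which(nchar(seqs) == 0L)[1L]])
  names(seqs) <- acc
  nonstd <- !grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"), seqs)
  if (any(nonstd))
    warning("non-standard residues in: ", paste(acc[nonstd], collapse = ", "))
  structure(seqs, class = "mva_proteome")
}

#' Write a proteome to FASTA
#'
#' @param proteome named character vector of sequences.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_fasta_proteome <- function(proteome, path) {
  aa <- Biostrings::AAStringSet(unclass(proteome))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Replicate correlation quality control
#'
#' Pearson correlation of two technical-replicate peptide count profiles
#' on the log10(count + 1) scale, over the union of their peptides (a
#' peptide absent from one replicate counts 0 there). Assay
#' reproducibility is summarised by this R; values near 0.87 are typical
#' for deep phage-display immunoprofiling replicates.
#'
#' @param profile_a,profile_b named numeric vectors, peptide -> count.
#' @return list with `r` (Pearson R), `p_value` (two-sided), `n_peptides`.
#' @export
replicate_correlation <- function(profile_a, profile_b) {
  stopifnot(length(profile_a) > 0L, length(profile_b) > 0L,
            !is.null(names(profile_a)), !is.null(names(profile_b)))
  peps <- union(names(profile_a), names(profile_b))
  if (length(peps) < 3L)
    stop("fewer than 3 peptides in the union; correlation undefined")
  a <- ifelse(peps %in% names(profile_a), profile_a[peps], 0)
  b <- ifelse(peps %in% names(profile_b), profile_b[peps], 0)
  a[is.na(a)] <- 0; b[is.na(b)] <- 0
  ct <- cor.test(log10(a + 1), log10(b + 1), method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n_peptides = length(peps))
}

#' Summarise a cohort for validation reporting
#'
#' @param cohort `mva_cohort`.
#' @return data.frame: subjects per CAD x perio cell plus per-subject
#'   peptide counts as attributes.
#' @export
cohort_summary <- function(cohort) {
  stopifnot(inherits(cohort, "mva_cohort"))
  tab <- as.data.frame(table(cad_group = cohort$subjects$cad_group,
                             perio_group = cohort$subjects$perio_group))
  names(tab)[3L] <- "n_subjects"
  pep <- tapply(cohort$counts$peptide, cohort$counts$subject_id, length)
  attr(tab, "peptides_per_subject") <- pep
  tab
}
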