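#' @importFrom stats setNames
NULL

#' The 20-letter amino-acid alphabet
#'
#' Standard one-letter codes for the 20 proteinogenic amino acids, the
#' alphabet of both the 12-mer peptide library and all proteome sequences.
#'
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Parse a wildcard sequence pattern
#'
#' Patterns describe short amino-acid motifs with three element kinds:
#' a fixed residue (`"P"`), a residue class (`"[ST]"`, two or more
#' alternative residues), and a single-position wildcard (`"."`).
#' `"P..T.PR"` therefore matches any 7-mer with P, T, P, R at positions
#' 1, 4, 6, 7.
#'
#' @param pattern pattern string, e.g. `"P..T.[P]R"`. A one-residue class
#'   `"[P]"` is accepted and treated as the fixed residue `P`.
#' @return an object of class `mva_pattern`: a list with `elements` (a list,
#'   one entry per position: a character vector of allowed residues, or
#'   `NA` for a wildcard), `length`, `n_fixed` (number of non-wildcard
#'   positions) and `string` (canonical printable form).
#' @examples
#' p <- parse_pattern("P..T.PR")
#' p$n_fixed  # 4
#' @export
parse_pattern <- function(pattern) {
  if (inherits(pattern, "mva_pattern")) return(pattern)
  stopifnot(is.character(pattern), length(pattern) == 1L, !is.na(pattern))
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  elements <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == ".") {
      elements[[length(elements) + 1L]] <- NA_character_
      i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L
      cls <- character()
      while (j <= length(chars) && chars[j] != "]") {
        if (!chars[j] %in% AA_ALPHABET)
          stop("invalid residue '", chars[j], "' in class of pattern '", pattern, "'")
        cls <- c(cls, chars[j])
        j <- j + 1L
      }
      if (j > length(chars)) stop("unterminated residue class in pattern '", pattern, "'")
      if (length(cls) == 0L) stop("empty residue class in pattern '", pattern, "'")
      elements[[length(elements) + 1L]] <- sort(unique(cls))
      i <- j + 1L
    } else if (ch %in% AA_ALPHABET) {
      elements[[length(elements) + 1L]] <- ch
      i <- i + 1L
    } else {
      stop("invalid character '", ch, "' in pattern '", pattern, "'")
    }
  }
  if (length(elements) == 0L) stop("empty pattern")
  is_wild <- vapply(elements, function(e) all(is.na(e)), logical(1))
  if (is_wild[1L] || is_wild[length(is_wild)])
    stop("pattern '", pattern, "' must not start or end with a wildcard (trimmed form)")
  n_fixed <- sum(!is_wild)
  structure(
    list(elements = elements, length = length(elements),
         n_fixed = n_fixed, string = pattern_string_from_elements(elements)),
    class = "mva_pattern"
  )
}

pattern_string_from_elements <- function(elements) {
  paste(vapply(elements, function(e) {
    if (all(is.na(e))) "." else if (length(e) == 1L) e
    else paste0("[", paste(e, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' @export
print.mva_pattern <- function(x, ...) {
  cat("<mva_pattern> ", x$string, "  (", x$n_fixed, " fixed / ",
      x$length, " positions)\n", sep = "")
  invisible(x)
}

#' @export
format.mva_pattern <- function(x, ...) x$string

#' Match a pattern against an amino-acid sequence
#'
#' Reports every offset at which all non-wildcard positions of the pattern
#' agree with the sequence; wildcards are always satisfied and residue
#' classes by membership. Matching is ungapped and the full pattern must
#' fit inside the sequence.
#'
#' @param pattern pattern string or `mva_pattern` object.
#' @param sequence amino-acid string (upper case).
#' @return integer vector of 0-based match offsets, increasing; empty if
#'   there is no match.
#' @examples
#' match_pattern("P..T.PR", "TLPMDTSPRAHW")  # 2
#' match_pattern("P..T.PR", "TLPMDASPRAHW")  # integer(0)
#' @export
match_pattern <- function(pattern, sequence) {
  p <- parse_pattern(pattern)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  n <- nchar(sequence)
  if (n < p$length) return(integer(0))
  sc <- strsplit(sequence, "", fixed = TRUE)[[1]]
  offs <- seq_len(n - p$length + 1L)  # 1-based start positions
  ok <- rep(TRUE, length(offs))
  for (i in seq_len(p$length)) {
    e <- p$elements[[i]]
    if (all(is.na(e))) next
    ok <- ok & sc[offs + i - 1L] %in% e
    if (!any(ok)) return(integer(0))
  }
  as.integer(offs[ok] - 1L)
}

#' Does a pattern occur anywhere in each of several sequences?
#'
#' @param pattern pattern string or `mva_pattern`.
#' @param sequences character vector of sequences.
#' @return logical vector, one per sequence.
#' @export
pattern_occurs <- function(pattern, sequences) {
  p <- parse_pattern(pattern)
  vapply(sequences, function(s) length(match_pattern(p, s)) > 0L,
         logical(1), USE.NAMES = FALSE)
}

#' Build a position weight matrix from equal-length sequences
#'
#' Residue frequencies per position over the 20-letter alphabet; columns
#' sum to one.
#'
#' @param seqs character vector of equal-length amino-acid strings.
#' @return 20 x L numeric matrix, rows named by residue.
#' @export
build_pwm <- function(seqs) {
  stopifnot(length(seqs) >= 1L)
  L <- nchar(seqs[1L])
  if (!all(nchar(seqs) == L)) stop("sequences must have equal length")
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  pwm <- vapply(seq_len(L), function(j) {
    tab <- table(factor(m[, j], levels = AA_ALPHABET))
    as.numeric(tab) / sum(tab)
  }, numeric(length(AA_ALPHABET)))
  rownames(pwm) <- AA_ALPHABET
  pwm
}

#' Consensus pattern string from a position weight matrix
#'
#' Per column: the majority residue (frequency >= `fixed_min`) becomes a
#' fixed position; otherwise all residues with frequency >= `class_min`
#' form a residue class; otherwise the position is a wildcard. Leading and
#' trailing wildcards are trimmed.
#'
#' @param pwm 20 x L matrix with columns summing to 1 (see [build_pwm()]).
#' @param fixed_min frequency above which a single residue is fixed (0.5).
#' @param class_min per-residue frequency for class membership (0.2).
#' @return consensus pattern string, e.g. `"P[AYS][LI]TA.[REQ][GT][LDK]"`.
#' @export
pwm_consensus <- function(pwm, fixed_min = 0.5, class_min = 0.2) {
  cols <- vapply(seq_len(ncol(pwm)), function(j) {
    f <- pwm[, j]
    if (max(f) >= fixed_min) {
      names(f)[which.max(f)]
    } else {
      cls <- sort(names(f)[f >= class_min])
      if (length(cls) >= 2L) paste0("[", paste(cls, collapse = ""), "]")
      else if (length(cls) == 1L) cls
      else "."
    }
  }, character(1))
  s <- paste(cols, collapse = "")
  sub("\\.+$", "", sub("^\\.+", "", s))
}
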