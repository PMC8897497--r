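#' @importFrom stats phyper wilcox.test
#' @importFrom utils combn
NULL

#' Select group-enriched peptides (the TopPeptide set)
#'
#' A peptide enters the group's TopPeptide set iff it is present
#' (count > 0) in at least 10% of the group's subjects (ceiling of
#' 0.1 * n) and reaches at least `min_count` reads in at least one of
#' them.
#'
#' @param cohort `mva_cohort`.
#' @param group clinical label: a CAD group (noCAD/sCAD/ACS) or a
#'   periodontal group (H/G/P).
#' @param min_subject_fraction presence fraction (default 0.10).
#' @param min_count abundance threshold (default 10 sequence counts).
#' @return character vector of peptides, sorted.
#' @export
select_group_peptides <- function(cohort, group,
                                  min_subject_fraction = 0.10,
                                  min_count = 10) {
  stopifnot(inherits(cohort, "mva_cohort"))
  sids <- subjects_in_group(cohort$subjects, group)
  if (length(sids) < 1L) stop("group '", group, "' has no subjects")
  cc <- cohort$counts[cohort$counts$subject_id %in% sids &
                        cohort$counts$count > 0, ]
  if (nrow(cc) == 0L) return(character(0))
  n_subj <- tapply(cc$subject_id, cc$peptide, function(x) length(unique(x)))
  max_cnt <- tapply(cc$count, cc$peptide, max)
  need <- ceiling(min_subject_fraction * length(sids))
  sort(names(n_subj)[n_subj >= need & max_cnt >= min_count])
}

subjects_in_group <- function(subjects, group) {
  if (group %in% CAD_GROUPS) subjects$subject_id[subjects$cad_group == group]
  else if (group %in% PERIO_GROUPS) subjects$subject_id[subjects$perio_group == group]
  else stop("unknown clinical group label '", group, "'")
}

#' Hypergeometric enrichment tail probability
#'
#' Upper-tail probability P(X >= k) for X ~ Hypergeometric(N, K, n):
#' the chance of observing at least `k` query matches when `n` query
#' sequences are drawn from a pool of `N` containing `K` matches in
#' total.
#'
#' @param k observed query matches.
#' @param K total matches in the pool.
#' @param n query size.
#' @param N pool size.
#' @return tail probability in (0, 1].
#' @export
hypergeometric_enrichment <- function(k, K, n, N) {
  stopifnot(length(k) == 1L, length(K) == 1L, length(n) == 1L, length(N) == 1L)
  if (K > N || n > N || k > min(K, n) || k < 0)
    stop("inconsistent hypergeometric margins: k=", k, " K=", K,
         " n=", n, " N=", N)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Exhaustive wildcard-motif discovery over a peptide query set
#'
#' Breadth-first expansion over the pattern trie: patterns grow to the
#' right by a fixed residue or a single-position wildcard, starting from
#' each residue. Query coverage (number of distinct query peptides
#' containing the pattern) is anti-monotone under extension, so any node
#' below `min_query_coverage` is pruned with its whole subtree. A pattern
#' is emitted iff it has at least `min_fixed_positions` non-wildcard
#' positions and a hypergeometric enrichment `p_hyper <
#' p_threshold` against the pooled query + reference sets. Emitted
#' patterns are deduplicated: among patterns matching the identical set
#' of query peptides only the most specific (most fixed positions, then
#' longest, then lexicographically first) is kept. After each iteration,
#' query peptides matched by any emitted pattern are removed and the
#' search re-runs on the remainder.
#'
#' @param query character vector of query peptides (equal length,
#'   typically 12-mers).
#' @param reference character vector of reference peptides.
#' @param min_query_coverage prune threshold on query coverage (4).
#' @param min_fixed_positions minimum fixed positions to emit (4).
#' @param p_threshold hypergeometric significance threshold (1e-5).
#' @param max_consecutive_wildcards maximum run of wildcards (3).
#' @param max_pattern_length maximum pattern length (the 12-mer frame).
#' @param n_iterations number of search/exclude iterations (2; the
#'   original workflow used 4 for very large inputs).
#' @return data.frame of motif records: `pattern`, `n_fixed`,
#'   `query_coverage`, `ref_coverage`, `p_hyper`, `enrichment_ratio`
#'   (query fraction over reference fraction with the reference count
#'   floored at 1), `iteration`. Sorted by iteration then p then pattern;
#'   invariant to the input order of peptides.
#' @export
discover_motifs <- function(query, reference,
                            min_query_coverage = 4,
                            min_fixed_positions = 4,
                            p_threshold = 1e-5,
                            max_consecutive_wildcards = 3,
                            max_pattern_length = 12,
                            n_iterations = 2) {
  stopifnot(n_iterations >= 1)
  empty <- data.frame(pattern = character(0), n_fixed = integer(0),
                      query_coverage = integer(0), ref_coverage = integer(0),
                      p_hyper = numeric(0), enrichment_ratio = numeric(0),
                      iteration = integer(0))
  query <- sort(unique(query)); reference <- sort(unique(reference))
  if (length(query) == 0L) return(empty)
  widths <- unique(nchar(c(query, reference)))
  if (length(widths) != 1L) stop("all peptides must have equal length")
  n_ref <- length(reference)
  rmat <- if (n_ref) do.call(rbind, strsplit(reference, "", fixed = TRUE)) else NULL

  out <- list()
  active <- query
  for (it in seq_len(n_iterations)) {
    if (length(active) < min_query_coverage) break
    res <- motif_search_once(active, rmat, n_query_total = length(active),
                             n_ref_total = n_ref,
                             min_query_coverage, min_fixed_positions,
                             p_threshold, max_consecutive_wildcards,
                             min(max_pattern_length, widths))
    if (nrow(res$records) == 0L) break
    res$records$iteration <- it
    out[[it]] <- res$records
    active <- setdiff(active, res$covered)
  }
  if (length(out) == 0L) return(empty)
  recs <- do.call(rbind, out)
  rownames(recs) <- NULL
  recs
}

# One full trie search on the active query set. Returns the emitted,
# deduplicated records plus the union of query peptides they cover.
motif_search_once <- function(query, rmat, n_query_total, n_ref_total,
                              min_cov, min_fixed, p_thr, max_wild, max_len) {
  qmat <- do.call(rbind, strsplit(query, "", fixed = TRUE))
  width <- ncol(qmat)
  N <- n_query_total + n_ref_total

  # root nodes: single fixed residues
  stack <- list()
  for (a in AA_ALPHABET) {
    w <- which(qmat == a, arr.ind = TRUE)
    if (nrow(w) == 0L) next
    qcov <- length(unique(w[, 1L]))
    if (qcov < min_cov) next
    rw <- if (!is.null(rmat)) which(rmat == a, arr.ind = TRUE) else
      matrix(integer(0), 0, 2)
    stack[[length(stack) + 1L]] <- list(
      pat = a, len = 1L, n_fixed = 1L, trail = 0L,
      qp = w[, 1L], qo = w[, 2L], rp = rw[, 1L], ro = rw[, 2L])
  }

  emitted <- list()
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL

    if (node$trail == 0L && node$n_fixed >= min_fixed) {
      k <- length(unique(node$qp))
      r <- if (length(node$rp)) length(unique(node$rp)) else 0L
      p <- hypergeometric_enrichment(k, k + r, n_query_total, N)
      if (p < p_thr) {
        ratio <- (k / n_query_total) / (max(r, 1L) / max(n_ref_total, 1L))
        emitted[[length(emitted) + 1L]] <-
          list(pattern = node$pat, n_fixed = node$n_fixed,
               query_coverage = k, ref_coverage = r, p_hyper = p,
               enrichment_ratio = ratio,
               qset = sort(unique(node$qp)))
      }
    }

    if (node$len >= max_len) next
    # next character of every occurrence that still fits in the frame
    fits <- node$qo + node$len <= width
    if (!any(fits)) next
    qp <- node$qp[fits]; qo <- node$qo[fits]
    nxt <- qmat[cbind(qp, qo + node$len)]
    rfits <- if (length(node$rp)) node$ro + node$len <= ncol(rmat) else logical(0)
    rp <- node$rp[rfits]; ro <- node$ro[rfits]
    rnxt <- if (length(rp)) rmat[cbind(rp, ro + node$len)] else character(0)

    parent_cov <- length(unique(node$qp))
    for (a in unique(nxt)) {
      sel <- nxt == a
      qcov <- length(unique(qp[sel]))
      stopifnot(qcov <= parent_cov)  # coverage anti-monotonicity
      if (qcov < min_cov) next
      rsel <- if (length(rnxt)) rnxt == a else logical(0)
      stack[[length(stack) + 1L]] <- list(
        pat = paste0(node$pat, a), len = node$len + 1L,
        n_fixed = node$n_fixed + 1L, trail = 0L,
        qp = qp[sel], qo = qo[sel], rp = rp[rsel], ro = ro[rsel])
    }
    # wildcard extension (internal only: needs room for a later fixed residue)
    if (node$trail < max_wild && node$len + 1L < max_len &&
        length(unique(qp)) >= min_cov) {
      stack[[length(stack) + 1L]] <- list(
        pat = paste0(node$pat, "."), len = node$len + 1L,
        n_fixed = node$n_fixed, trail = node$trail + 1L,
        qp = qp, qo = qo, rp = rp, ro = ro)
    }
  }

  if (length(emitted) == 0L)
    return(list(records = data.frame(pattern = character(0),
                                     n_fixed = integer(0),
                                     query_coverage = integer(0),
                                     ref_coverage = integer(0),
                                     p_hyper = numeric(0),
                                     enrichment_ratio = numeric(0)),
                covered = character(0)))

  # maximality: one most-specific representative per query match set
  keys <- vapply(emitted, function(e) paste(e$qset, collapse = ","), character(1))
  keep <- unlist(lapply(split(seq_along(emitted), keys), function(idx) {
    nf <- vapply(emitted[idx], `[[`, 0L, "n_fixed")
    idx <- idx[nf == max(nf)]
    ln <- nchar(vapply(emitted[idx], `[[`, "", "pattern"))
    idx <- idx[ln == max(ln)]
    idx[order(vapply(emitted[idx], `[[`, "", "pattern"))][1L]
  }), use.names = FALSE)
  emitted <- emitted[sort(keep)]

  records <- data.frame(
    pattern = vapply(emitted, `[[`, "", "pattern"),
    n_fixed = vapply(emitted, `[[`, 0L, "n_fixed"),
    query_coverage = vapply(emitted, `[[`, 0L, "query_coverage"),
    ref_coverage = vapply(emitted, `[[`, 0L, "ref_coverage"),
    p_hyper = vapply(emitted, `[[`, 0, "p_hyper"),
    enrichment_ratio = vapply(emitted, `[[`, 0, "enrichment_ratio"),
    stringsAsFactors = FALSE)
  ord <- order(records$p_hyper, records$pattern)
  records <- records[ord, ]
  rownames(records) <- NULL
  covered <- query[sort(unique(unlist(lapply(emitted, `[[`, "qset"))))]
  list(records = records, covered = covered)
}

#' Apply the strict TopMotif filter
#'
#' A motif survives iff its hypergeometric p is below `p_threshold` OR
#' its query/reference enrichment ratio is at least `ratio_threshold`
#' (a disjunction: either arm suffices).
#'
#' @param motifs data.frame from [discover_motifs()].
#' @param p_threshold strict significance threshold (1e-8).
#' @param ratio_threshold query/reference ratio threshold (10).
#' @return filtered data.frame, input order preserved.
#' @export
select_top_motifs <- function(motifs, p_threshold = 1e-8,
                              ratio_threshold = 10) {
  stopifnot(all(c("p_hyper", "enrichment_ratio") %in% names(motifs)))
  motifs[motifs$p_hyper < p_threshold |
           motifs$enrichment_ratio >= ratio_threshold, , drop = FALSE]
}

#' Per-subject motif abundance matrix
#'
#' Entry (motif, subject) is the summed read count of the subject's
#' peptides that contain the motif.
#'
#' @param motifs character vector of pattern strings (or list of
#'   `mva_pattern`).
#' @param cohort `mva_cohort`.
#' @return numeric matrix, motifs (rows, named by pattern string) x
#'   subjects (columns).
#' @export
motif_abundance <- function(motifs, cohort) {
  stopifnot(inherits(cohort, "mva_cohort"))
  pats <- lapply(motifs, parse_pattern)
  pat_str <- vapply(pats, `[[`, "", "string")
  sids <- cohort$subjects$subject_id
  peps <- unique(cohort$counts$peptide)
  m <- matrix(0, nrow = length(pats), ncol = length(sids),
              dimnames = list(pat_str, sids))
  if (length(peps) == 0L || length(pats) == 0L) return(m)
  sub_f <- factor(cohort$counts$subject_id, levels = sids)
  for (i in seq_along(pats)) {
    hit_peps <- peps[pattern_occurs(pats[[i]], peps)]
    if (!length(hit_peps)) next
    rows <- cohort$counts$peptide %in% hit_peps
    s <- tapply(cohort$counts$count[rows], sub_f[rows], sum, default = 0)
    m[i, ] <- as.numeric(s)
  }
  m
}

#' Select group-differential motifs
#'
#' A motif is group-differential for a contrast iff all three of:
#' (i) the mean abundance in one contrast group exceeds `fold` times the
#' mean in the other; (ii) some abundance threshold separates the groups
#' with sensitivity >= `min_sens` and specificity >= `min_spec`
#' (thresholds swept over the observed values, ">= threshold" calling
#' the higher-mean group); (iii) a two-sided Mann-Whitney U test at
#' `alpha` (exact when both groups have <= 8 subjects and no ties,
#' tie-corrected normal approximation otherwise).
#'
#' @param abundance matrix from [motif_abundance()] (motifs x subjects).
#' @param subjects subject metadata data.frame.
#' @param contrast character vector of two clinical labels, e.g.
#'   `c("P", "H")` or `c("ACS", "noCAD")`.
#' @param fold mean fold-change criterion (3).
#' @param min_sens,min_spec separation criterion (0.5, 0.7).
#' @param alpha Mann-Whitney significance level (0.05).
#' @return data.frame with one row per motif: `pattern`, the three
#'   criterion flags (`pass_fold`, `pass_sep`, `pass_mwu`), supporting
#'   values (`mean_a`, `mean_b`, `best_sens`, `best_spec`, `p_mwu`) and
#'   `differential` (all three criteria met).
#' @export
select_group_differential <- function(abundance, subjects, contrast,
                                      fold = 3, min_sens = 0.5,
                                      min_spec = 0.7, alpha = 0.05) {
  stopifnot(length(contrast) == 2L)
  ids_a <- subjects_in_group(subjects, contrast[1L])
  ids_b <- subjects_in_group(subjects, contrast[2L])
  if (length(ids_a) < 2L || length(ids_b) < 2L)
    stop("each contrast group needs >= 2 subjects")
  a <- abundance[, ids_a, drop = FALSE]
  b <- abundance[, ids_b, drop = FALSE]
  res <- lapply(seq_len(nrow(abundance)), function(i) {
    xa <- a[i, ]; xb <- b[i, ]
    ma <- mean(xa); mb <- mean(xb)
    pass_fold <- (ma > fold * mb) || (mb > fold * ma)
    hi <- if (ma >= mb) xa else xb
    lo <- if (ma >= mb) xb else xa
    sweep <- threshold_sweep(hi, lo)
    pass_sep <- any(sweep$sens >= min_sens & sweep$spec >= min_spec)
    best <- which.max(pmin(sweep$sens / min_sens, sweep$spec / min_spec))
    p_mwu <- mwu_two_sided(xa, xb)
    data.frame(pattern = rownames(abundance)[i],
               mean_a = ma, mean_b = mb,
               pass_fold = pass_fold,
               best_sens = sweep$sens[best], best_spec = sweep$spec[best],
               pass_sep = pass_sep,
               p_mwu = p_mwu, pass_mwu = p_mwu < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$differential <- out$pass_fold & out$pass_sep & out$pass_mwu
  rownames(out) <- NULL
  out
}

# sens/spec of the rule "value >= t calls positive" for every candidate
# threshold t among the observed values (plus one above the maximum).
threshold_sweep <- function(pos, neg) {
  cand <- sort(unique(c(pos, neg, max(pos, neg) + 1)))
  sens <- vapply(cand, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(neg < t), numeric(1))
  list(threshold = cand, sens = sens, spec = spec)
}

# Two-sided Mann-Whitney U p-value: exact enumeration over all
# C(n1+n2, n1) group assignments when both groups are small (handles
# ties, which the usual exact algorithm cannot), tie-corrected normal
# approximation otherwise.
mwu_two_sided <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 <= 8L && n2 <= 8L) {
    z <- c(x, y)
    mu <- n1 * n2 / 2
    u_of <- function(idx) {
      a <- z[idx]; b <- z[-idx]
      sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    }
    u_obs <- u_of(seq_len(n1))
    us <- combn(n1 + n2, n1, u_of)
    mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
  } else {
    suppressWarnings(
      wilcox.test(x, y, alternative = "two.sided", exact = FALSE,
                  correct = TRUE)$p.value)
  }
}
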