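#' @importFrom stats cor hclust cutree as.dist quantile sd
NULL

#' Best ungapped similarity of two patterns
#'
#' The maximum, over all ungapped relative offsets, of the number of
#' aligned positions at which both patterns carry the same fixed residue
#' (wildcards and residue classes do not count).
#'
#' @param a,b pattern strings or `mva_pattern` objects.
#' @return integer similarity.
#' @export
pattern_similarity <- function(a, b) {
  pa <- parse_pattern(a); pb <- parse_pattern(b)
  fa <- vapply(pa$elements, function(e)
    if (length(e) == 1L && !is.na(e)) e else NA_character_, character(1))
  fb <- vapply(pb$elements, function(e)
    if (length(e) == 1L && !is.na(e)) e else NA_character_, character(1))
  best <- 0L
  for (shift in (-(length(fb) - 1L)):(length(fa) - 1L)) {
    ia <- seq_along(fa)
    ib <- ia - shift
    ok <- ib >= 1L & ib <= length(fb)
    if (!any(ok)) next
    s <- sum(!is.na(fa[ia[ok]]) & !is.na(fb[ib[ok]]) &
               fa[ia[ok]] == fb[ib[ok]])
    best <- max(best, s)
  }
  best
}

#' Cluster motifs by sequence homology
#'
#' Two motifs are homologous if they share at least `min_shared`
#' identical fixed residues at some ungapped offset. Clusters are the
#' single-linkage connected components of this relation; components
#' smaller than `min_cluster` are set aside as unclustered.
#'
#' @param motifs character vector of non-redundant pattern strings.
#' @param min_shared minimum shared identical positions (3).
#' @param min_cluster minimum motifs per retained cluster (3).
#' @return list with `clusters` (list of lists: `cluster_id`, `members`,
#'   `consensus`) and `unclustered` (character vector of members of
#'   too-small components).
#' @export
cluster_motifs_by_homology <- function(motifs, min_shared = 3,
                                       min_cluster = 3) {
  motifs <- unique(as.character(motifs))
  n <- length(motifs)
  if (n == 0L) return(list(clusters = list(), unclustered = character(0)))
  # union-find over homologous pairs
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    pats <- lapply(motifs, parse_pattern)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (pattern_similarity(pats[[i]], pats[[j]]) >= min_shared) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  comps <- split(motifs, roots)
  comps <- comps[order(-vapply(comps, length, 0L),
                       vapply(comps, `[`, "", 1L))]
  keep <- vapply(comps, length, 0L) >= min_cluster
  clusters <- lapply(seq_along(comps[keep]), function(i) {
    members <- sort(comps[keep][[i]])
    list(cluster_id = i, members = members,
         consensus = consensus_from_patterns(members))
  })
  list(clusters = clusters,
       unclustered = sort(unlist(comps[!keep], use.names = FALSE)))
}

#' Consensus pattern of a set of homologous patterns
#'
#' Members are aligned ungapped against an anchor (the member with the
#' most fixed positions) at their best-similarity offset; fixed residues
#' are stacked into per-column frequencies and summarised with the usual
#' consensus rule (>= 0.5 fixed, >= 0.2 class member, else wildcard).
#'
#' @param patterns character vector of pattern strings.
#' @return consensus pattern string.
#' @export
consensus_from_patterns <- function(patterns) {
  pats <- lapply(patterns, parse_pattern)
  if (length(pats) == 1L) return(pats[[1L]]$string)
  nf <- vapply(pats, `[[`, 0L, "n_fixed")
  anchor <- pats[[which.max(nf)]]
  offs <- vapply(pats, function(p) best_offset(anchor, p), 0L)
  lo <- min(offs); hi <- max(offs + vapply(pats, `[[`, 0L, "length") - 1L)
  ncol_ <- hi - lo + 1L
  counts <- matrix(0, nrow = length(AA_ALPHABET), ncol = ncol_,
                   dimnames = list(AA_ALPHABET, NULL))
  for (i in seq_along(pats)) {
    p <- pats[[i]]
    for (j in seq_len(p$length)) {
      e <- p$elements[[j]]
      if (length(e) == 1L && !is.na(e))
        counts[e, offs[i] - lo + j] <- counts[e, offs[i] - lo + j] + 1
    }
  }
  tot <- colSums(counts)
  freq <- counts
  freq[, tot > 0] <- sweep(counts[, tot > 0, drop = FALSE], 2,
                           tot[tot > 0], "/")
  pwm_consensus(freq)
}

# offset of p relative to the anchor maximising shared fixed residues
best_offset <- function(anchor, p) {
  fa <- vapply(anchor$elements, function(e)
    if (length(e) == 1L && !is.na(e)) e else NA_character_, character(1))
  fp <- vapply(p$elements, function(e)
    if (length(e) == 1L && !is.na(e)) e else NA_character_, character(1))
  best <- 0L; best_s <- -1L
  for (shift in (-(length(fp) - 1L)):(length(fa) - 1L)) {
    ia <- seq_along(fa); ip <- ia - shift
    ok <- ip >= 1L & ip <= length(fp)
    if (!any(ok)) next
    s <- sum(!is.na(fa[ia[ok]]) & !is.na(fp[ip[ok]]) &
               fa[ia[ok]] == fp[ip[ok]])
    if (s > best_s) { best_s <- s; best <- shift }
  }
  as.integer(best)
}

#' Per-subject abundance of motif clusters
#'
#' For each cluster and subject, the summed count of the subject's
#' peptides matched by at least one member motif; a peptide matched by
#' several members of the same cluster is counted once.
#'
#' @param clusters list of clusters as in [cluster_motifs_by_homology()].
#' @param cohort `mva_cohort`.
#' @return numeric matrix, clusters (rows, named `cluster_<id>`) x
#'   subjects.
#' @export
cluster_abundance <- function(clusters, cohort) {
  stopifnot(inherits(cohort, "mva_cohort"))
  sids <- cohort$subjects$subject_id
  peps <- unique(cohort$counts$peptide)
  m <- matrix(0, nrow = length(clusters), ncol = length(sids),
              dimnames = list(vapply(clusters, function(cl)
                paste0("cluster_", cl$cluster_id), ""), sids))
  sub_f <- factor(cohort$counts$subject_id, levels = sids)
  for (i in seq_along(clusters)) {
    hit <- rep(FALSE, length(peps))
    for (mem in clusters[[i]]$members)
      hit <- hit | pattern_occurs(mem, peps)
    if (!any(hit)) next
    rows <- cohort$counts$peptide %in% peps[hit]
    s <- tapply(cohort$counts$count[rows], sub_f[rows], sum, default = 0)
    m[i, ] <- as.numeric(s)
  }
  m
}

#' Default clinical strata for the group x cluster abundance matrix
#'
#' CAD groups, periodontal groups, smoking exposure (never vs any
#' exposure) and diabetes status.
#'
#' @param subjects subject metadata data.frame.
#' @return named list of subject-id vectors.
#' @export
default_strata <- function(subjects) {
  list(
    noCAD = subjects$subject_id[subjects$cad_group == "noCAD"],
    sCAD  = subjects$subject_id[subjects$cad_group == "sCAD"],
    ACS   = subjects$subject_id[subjects$cad_group == "ACS"],
    H = subjects$subject_id[subjects$perio_group == "H"],
    G = subjects$subject_id[subjects$perio_group == "G"],
    P = subjects$subject_id[subjects$perio_group == "P"],
    `smoking-` = subjects$subject_id[subjects$smoking == "never"],
    `smoking+` = subjects$subject_id[subjects$smoking != "never"],
    `DM-` = subjects$subject_id[!subjects$diabetes],
    `DM+` = subjects$subject_id[subjects$diabetes]
  )
}

#' Group-normalised cluster abundance matrix
#'
#' Cell (cluster, group) is the mean cluster abundance over the group's
#' subjects, divided by the mean of the group means for that cluster, so
#' every retained row averages to 1. Clusters whose cross-group mean
#' abundance falls below `min_mean` are dropped before normalisation.
#' Row and column dendrogram orders (Pearson correlation distance,
#' Ward-D2 linkage) are attached for presentation.
#'
#' @param abundance clusters x subjects matrix from [cluster_abundance()].
#' @param strata named list of subject-id vectors (see
#'   [default_strata()]).
#' @param min_mean abundance floor (150).
#' @return clusters x strata matrix with attributes `row_order` and
#'   `col_order`.
#' @export
group_abundance_matrix <- function(abundance, strata, min_mean = 150) {
  empty <- vapply(strata, length, 0L) == 0L
  if (any(empty))
    stop("empty stratum: ", paste(names(strata)[empty], collapse = ", "))
  gm <- vapply(strata, function(ids)
    rowMeans(abundance[, ids, drop = FALSE]), numeric(nrow(abundance)))
  if (nrow(abundance) == 1L) gm <- matrix(gm, nrow = 1,
                                          dimnames = list(rownames(abundance),
                                                          names(strata)))
  keep <- rowMeans(gm) >= min_mean
  gm <- gm[keep, , drop = FALSE]
  norm <- gm / rowMeans(gm)
  attr(norm, "row_order") <- presentation_order(norm)
  attr(norm, "col_order") <- presentation_order(t(norm))
  norm
}

presentation_order <- function(m) {
  if (nrow(m) < 3L) return(seq_len(nrow(m)))
  r <- suppressWarnings(cor(t(m)))
  r[is.na(r)] <- 0
  hclust(as.dist(1 - r), method = "ward.D2")$order
}

#' Unite motif clusters into correlation-defined epitope groups
#'
#' Per-subject cluster abundances are log10(x + 1) transformed; pairwise
#' Pearson correlations over subjects define the distance 1 - R, and
#' Ward-D2 agglomeration cut at `k` groups yields the epitope groups.
#' Labels A, B, ... are assigned in descending order of total (summed)
#' abundance. A constant abundance vector has undefined correlation; it
#' is assigned by the zero-correlation convention with a warning.
#'
#' @param abundance clusters x subjects matrix from [cluster_abundance()].
#' @param k number of epitope groups (5).
#' @param cluster_consensus optional named character vector (cluster id
#'   -> consensus pattern) used to derive each group's core consensus.
#' @return list with `epitopes` (list per label: `label`, `cluster_ids`,
#'   `core_consensus`, `per_subject_abundance`), `assignments` (named
#'   vector cluster -> label) and `correlation` (full matrix).
#' @export
define_epitopes <- function(abundance, k = 5, cluster_consensus = NULL) {
  stopifnot(nrow(abundance) >= k)
  lx <- log10(abundance + 1)
  sds <- apply(lx, 1L, function(v) sd(v))
  if (any(sds == 0))
    warning("constant abundance vector(s): ",
            paste(rownames(abundance)[sds == 0], collapse = ", "),
            "; assigned by zero-correlation convention")
  r <- suppressWarnings(cor(t(lx)))
  r[is.na(r)] <- 0
  diag(r) <- 1
  hc <- hclust(as.dist(1 - r), method = "ward.D2")
  grp <- cutree(hc, k = k)
  totals <- tapply(rowSums(abundance), grp, sum)
  lab_order <- order(-totals)
  labels <- setNames(LETTERS[seq_len(k)], names(totals)[lab_order])
  assignments <- setNames(labels[as.character(grp)], rownames(abundance))
  epitopes <- lapply(LETTERS[seq_len(k)], function(L) {
    ids <- names(assignments)[assignments == L]
    cons <- if (!is.null(cluster_consensus)) {
      cc <- cluster_consensus[ids]
      cc <- cc[!is.na(cc)]
      if (length(cc)) consensus_from_patterns(cc) else NA_character_
    } else NA_character_
    list(label = L, cluster_ids = ids, core_consensus = cons,
         per_subject_abundance = colSums(abundance[ids, , drop = FALSE]))
  })
  names(epitopes) <- LETTERS[seq_len(k)]
  list(epitopes = epitopes, assignments = assignments, correlation = r)
}
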