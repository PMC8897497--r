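#' Tile a proteome into 20-aa fragments in two frameshifts
#'
#' Frameshift 0 windows start at 0, 20, 40, ...; frameshift -10 windows
#' at 10, 30, 50, ... Only complete 20-aa windows are emitted, so the two
#' tilings overlap by 10 residues and between them catch motif hits that
#' straddle either tiling's boundaries.
#'
#' @param proteome `mva_proteome` or named character vector of sequences.
#' @return data.frame: `accession`, `start` (0-based inclusive), `end`
#'   (exclusive), `frameshift` (0 or -10).
#' @export
tile_fragments <- function(proteome) {
  rows <- lapply(names(proteome), function(acc) {
    L <- nchar(proteome[[acc]])
    if (L < 20L) return(NULL)
    s0 <- seq(0L, L - 20L, by = 20L)
    s1 <- if (L >= 30L) seq(10L, L - 20L, by = 20L) else integer(0)
    data.frame(accession = acc,
               start = c(s0, s1), end = c(s0, s1) + 20L,
               frameshift = rep(c(0L, -10L), c(length(s0), length(s1))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(accession = character(0), start = integer(0),
                      end = integer(0), frameshift = integer(0))
  rownames(out) <- NULL
  out
}

#' Align motifs to a proteome
#'
#' An alignment requires every fixed position of the motif to match the
#' protein exactly; wildcards are unconstrained. Motifs with fewer than
#' `min_fixed` fixed positions are rejected.
#'
#' @param motifs character vector of pattern strings.
#' @param proteome `mva_proteome` or named character vector.
#' @param min_fixed minimum fixed positions per motif (4).
#' @return data.frame of hits: `pattern`, `accession`, `offset`
#'   (0-based), `span_end` (exclusive).
#' @export
align_motifs_to_proteome <- function(motifs, proteome, min_fixed = 4) {
  pats <- lapply(motifs, parse_pattern)
  nf <- vapply(pats, `[[`, 0L, "n_fixed")
  if (any(nf < min_fixed))
    stop("motif with < ", min_fixed, " fixed positions: ",
         vapply(pats[nf < min_fixed], `[[`, "", "string")[1L])
  rows <- list()
  for (p in pats) {
    for (acc in names(proteome)) {
      offs <- match_pattern(p, proteome[[acc]])
      if (length(offs))
        rows[[length(rows) + 1L]] <- data.frame(
          pattern = p$string, accession = acc, offset = offs,
          span_end = offs + p$length, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pattern = character(0), accession = character(0),
               offset = integer(0), span_end = integer(0))
  rownames(out) <- NULL
  out
}

# The candidate fragment of one tiling that could fully contain a span
# [o, e) on a protein: returns its 0-based start, or NA if the span
# straddles that tiling's boundary.
containing_fragment_start <- function(offset, span_end, frameshift) {
  base <- if (frameshift == 0L) 0L else 10L
  if (offset < base) return(NA_integer_)
  fs <- base + 20L * ((offset - base) %/% 20L)
  if (span_end <= fs + 20L) fs else NA_integer_
}

#' Alignment load of proteome fragments
#'
#' Load of a fragment for a subject is the mean abundance of the distinct
#' motifs aligned inside it:
#' sum of abundances of motifs aligned / count of motifs aligned.
#' A hit counts toward a fragment only if its span lies fully within the
#' fragment; a motif hitting one fragment at several offsets is counted
#' once. Fragments with no hits have load 0. The total load of a fragment
#' is the sum of its per-subject loads.
#'
#' @param hits data.frame from [align_motifs_to_proteome()].
#' @param fragments data.frame from [tile_fragments()] (any subset, e.g.
#'   merged 30-aa fragments with `frameshift = NA`).
#' @param abundance motif x subject matrix from [motif_abundance()];
#'   every hit pattern must have a row.
#' @return list of class `mva_loads`: `fragments` (the input data.frame
#'   with a `fragment_id` column), `per_subject` (fragment x subject
#'   load matrix), `total` (named numeric, summed over subjects), and
#'   `fragment_motifs` (list of distinct patterns per fragment).
#' @export
fragment_alignment_load <- function(hits, fragments, abundance) {
  miss <- setdiff(unique(hits$pattern), rownames(abundance))
  if (length(miss))
    stop("no abundance row for motif(s): ", paste(miss, collapse = ", "))
  fragments <- as.data.frame(fragments)
  fragments$fragment_id <- sprintf("%s:%d-%d", fragments$accession,
                                   fragments$start, fragments$end)
  fkey <- fragments$fragment_id
  # distinct motifs per fragment
  frag_motifs <- setNames(vector("list", nrow(fragments)), fkey)
  if (nrow(hits)) {
    for (i in seq_len(nrow(hits))) {
      acc <- hits$accession[i]; o <- hits$offset[i]; e <- hits$span_end[i]
      sel <- fragments$accession == acc & fragments$start <= o &
        e <= fragments$end
      for (id in fkey[sel]) frag_motifs[[id]] <- c(frag_motifs[[id]],
                                                   hits$pattern[i])
    }
    frag_motifs <- lapply(frag_motifs, unique)
  }
  per_subject <- matrix(0, nrow = nrow(fragments), ncol = ncol(abundance),
                        dimnames = list(fkey, colnames(abundance)))
  for (id in fkey) {
    ms <- frag_motifs[[id]]
    if (length(ms) == 0L) next
    per_subject[id, ] <- colSums(abundance[ms, , drop = FALSE]) / length(ms)
  }
  structure(list(fragments = fragments, per_subject = per_subject,
                 total = rowSums(per_subject), fragment_motifs = frag_motifs),
            class = "mva_loads")
}

#' Select the top-loaded fragments, merging side-by-side pairs
#'
#' Fragments are ranked by total alignment load (descending; ties broken
#' by accession then start for determinism) and the top `k` retained.
#' When a selected 20-aa fragment overlaps a previously selected one from
#' the other frameshift by 10 residues, the pair is replaced by a single
#' 30-aa fragment spanning their union, with its load recomputed over the
#' merged span.
#'
#' @param loads `mva_loads` from [fragment_alignment_load()].
#' @param hits the hits used to build `loads` (needed to recompute merged
#'   loads).
#' @param abundance the motif x subject abundance matrix.
#' @param k number of fragments to return (default 40).
#' @return data.frame: `accession`, `start`, `end`, `frameshift` (NA for
#'   merged 30-aa fragments), `total_load`, ranked by load.
#' @export
select_top_fragments <- function(loads, hits, abundance, k = 40) {
  stopifnot(inherits(loads, "mva_loads"), k >= 1)
  fr <- loads$fragments
  fr$total_load <- unname(loads$total[fr$fragment_id])
  ord <- order(-fr$total_load, fr$accession, fr$start)
  fr <- fr[ord, ]

  sel <- list()
  for (i in seq_len(nrow(fr))) {
    if (length(sel) >= k) break
    cand <- fr[i, ]
    if (cand$total_load <= 0) break
    merged <- FALSE
    for (j in seq_along(sel)) {
      s <- sel[[j]]
      if (!is.na(s$frameshift) && s$accession == cand$accession &&
          s$frameshift != cand$frameshift &&
          abs(s$start - cand$start) == 10L) {
        ms <- min(s$start, cand$start)
        sel[[j]] <- merged_fragment_row(cand$accession, ms, ms + 30L,
                                        hits, abundance)
        merged <- TRUE
        break
      }
    }
    if (!merged)
      sel[[length(sel) + 1L]] <- data.frame(
        accession = cand$accession, start = cand$start, end = cand$end,
        frameshift = cand$frameshift, total_load = cand$total_load,
        stringsAsFactors = FALSE)
  }
  out <- if (length(sel)) do.call(rbind, sel) else
    data.frame(accession = character(0), start = integer(0),
               end = integer(0), frameshift = integer(0),
               total_load = numeric(0))
  out <- out[order(-out$total_load, out$accession, out$start), ]
  rownames(out) <- NULL
  out
}

merged_fragment_row <- function(acc, start, end, hits, abundance) {
  sel <- hits$accession == acc & hits$offset >= start & hits$span_end <= end
  ms <- unique(hits$pattern[sel])
  total <- if (length(ms))
    sum(colSums(abundance[ms, , drop = FALSE]) / length(ms)) else 0
  data.frame(accession = acc, start = start, end = end,
             frameshift = NA_integer_, total_load = total,
             stringsAsFactors = FALSE)
}

#' Cluster aligned 12-mer substrings into target types
#'
#' For every motif hit inside a top fragment, the 12-residue protein
#' substring centred on the hit span (shifted inward at fragment edges)
#' is extracted. Unique substrings are clustered by greedy agglomeration:
#' a substring joins the first cluster in which some member is within
#' `distance_cutoff` Hamming distance (ungapped, offset 0; a cutoff of 9
#' over 12 positions demands at least 3 identities). Clusters with fewer
#' than `min_cluster` unique substrings are discarded ("no counts":
#' multiplicity of an identical substring does not help a cluster).
#' Each surviving cluster gets a position weight matrix and a consensus
#' pattern.
#'
#' @param top_fragments data.frame from [select_top_fragments()].
#' @param hits data.frame from [align_motifs_to_proteome()].
#' @param proteome the proteome the hits refer to.
#' @param min_cluster minimum unique substrings per cluster (10).
#' @param distance_cutoff maximum Hamming distance for joining (9).
#' @return list of target types, each a list with `member_substrings`,
#'   `pwm` (20 x 12, columns sum to 1), `consensus`, `n_members`;
#'   ordered by decreasing size.
#' @export
cluster_target_types <- function(top_fragments, hits, proteome,
                                 min_cluster = 10, distance_cutoff = 9) {
  stopifnot(nrow(top_fragments) >= 1L)
  subs <- character(0)
  for (i in seq_len(nrow(hits))) {
    acc <- hits$accession[i]; o <- hits$offset[i]; e <- hits$span_end[i]
    fr <- top_fragments[top_fragments$accession == acc &
                          top_fragments$start <= o &
                          e <= top_fragments$end, , drop = FALSE]
    if (nrow(fr) == 0L) next
    fs <- fr$start[1L]; fe <- fr$end[1L]
    centre <- (o + e) / 2
    s12 <- round(centre - 6)
    s12 <- max(fs, min(s12, fe - 12L))
    if (s12 < fs || s12 + 12L > fe) next  # fragment cannot host a 12-mer
    subs <- c(subs, substr(proteome[[acc]], s12 + 1L, s12 + 12L))
  }
  subs <- sort(unique(subs))
  if (length(subs) == 0L) return(list())
  clusters <- greedy_hamming_clusters(subs, distance_cutoff)
  clusters <- clusters[vapply(clusters, length, 0L) >= min_cluster]
  out <- lapply(clusters, function(members) {
    pwm <- build_pwm(members)
    list(member_substrings = members, pwm = pwm,
         consensus = pwm_consensus(pwm), n_members = length(members))
  })
  out[order(-vapply(out, `[[`, 0L, "n_members"))]
}

greedy_hamming_clusters <- function(seqs, cutoff) {
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  clusters <- list()  # each: integer indices into seqs
  for (i in seq_along(seqs)) {
    joined <- FALSE
    for (j in seq_along(clusters)) {
      members <- clusters[[j]]
      d <- colSums(t(m[members, , drop = FALSE]) != m[i, ])
      if (min(d) <= cutoff) {
        clusters[[j]] <- c(members, i)
        joined <- TRUE
        break
      }
    }
    if (!joined) clusters[[length(clusters) + 1L]] <- i
  }
  lapply(clusters, function(idx) seqs[idx])
}
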