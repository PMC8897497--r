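test_that("two-frameshift tiling emits only complete 20-aa windows", {
  prot <- c(p1 = paste(rep("A", 60), collapse = ""))
  fr <- tile_fragments(prot)
  expect_equal(fr$start[fr$frameshift == 0], c(0L, 20L, 40L))
  expect_equal(fr$start[fr$frameshift == -10], c(10L, 30L))
  expect_equal(nrow(fr), 5L)
  expect_true(all(fr$end - fr$start == 20L))

  short <- c(p1 = paste(rep("A", 19), collapse = ""))
  expect_equal(nrow(tile_fragments(short)), 0L)
})

test_that("each tiling partitions its covered range", {
  pp <- plant_proteome(n_proteins = 7, length_range = c(45, 130),
                       target = NULL, seed = 3)
  fr <- tile_fragments(pp$proteome)
  # brute-force window count oracle
  expected <- sum(vapply(pp$proteome, function(s) {
    L <- nchar(s)
    length(seq(0, L - 20, by = 20)) +
      if (L >= 30) length(seq(10, L - 20, by = 20)) else 0L
  }, numeric(1)))
  expect_equal(nrow(fr), expected)
  for (acc in names(pp$proteome)) {
    for (fs in c(0L, -10L)) {
      w <- fr[fr$accession == acc & fr$frameshift == fs, ]
      if (nrow(w) == 0) next
      covered <- unlist(Map(seq, w$start, w$end - 1L))
      expect_equal(anyDuplicated(covered), 0L)  # partition: no overlap
      expect_equal(sort(covered), seq(min(w$start), max(w$end) - 1L))
    }
  }
})

test_that("motif-to-proteome alignment matches the regex oracle", {
  withr::with_seed(41, {
    pp <- plant_proteome(n_proteins = 20, length_range = c(60, 150),
                         target = NULL, seed = 41)
    motifs <- unique(replicate(15, random_test_pattern(4, 8)))
    motifs <- motifs[vapply(motifs, function(m)
      parse_pattern(m)$n_fixed >= 4, logical(1))]
    hits <- align_motifs_to_proteome(motifs, pp$proteome)
    for (m in motifs) for (acc in names(pp$proteome)) {
      expect_equal(hits$offset[hits$pattern == parse_pattern(m)$string &
                                 hits$accession == acc],
                   regex_match_oracle(m, pp$proteome[[acc]]))
    }
  })
  expect_error(align_motifs_to_proteome("P.R", c(p = "APRA")), "fixed positions")
})

test_that("the epitope-bearing protein segment is hit at the printed offset", {
  prot <- c(vp = paste0(paste(rep("G", 30), collapse = ""), "TLPMDTSPRAHW",
                        paste(rep("G", 18), collapse = "")))
  hits <- align_motifs_to_proteome("P..T.PR", prot)
  expect_equal(hits$offset, 32L)  # the P of TLP...
})

test_that("alignment load implements the mean-abundance formula", {
  prot <- c(p1 = paste(rep("A", 40), collapse = ""))
  fr <- tile_fragments(prot)
  hits <- data.frame(pattern = c("m1", "m2", "m3"), accession = "p1",
                     offset = c(0L, 5L, 12L), span_end = c(6L, 11L, 18L))
  ab <- matrix(c(100, 50, 30), nrow = 3, dimnames = list(c("m1", "m2", "m3"), "S1"))
  lm <- fragment_alignment_load(hits, fr, ab)
  expect_equal(unname(lm$total["p1:0-20"]), (100 + 50 + 30) / 3)  # = 60
  # single motif with zero abundance: load 0
  lm0 <- fragment_alignment_load(hits[1, ], fr, ab * 0)
  expect_equal(unname(lm0$total["p1:0-20"]), 0)
  expect_error(fragment_alignment_load(
    data.frame(pattern = "zz", accession = "p1", offset = 0L, span_end = 5L),
    fr, ab), "no abundance row")
})

test_that("alignment load equals brute-force recomputation", {
  withr::with_seed(43, {
    pp <- plant_proteome(n_proteins = 10, length_range = c(50, 120),
                         target = NULL, seed = 43)
    motifs <- c("P..T.PR", unique(replicate(9, random_test_pattern(4, 7))))
    motifs <- Filter(function(m) parse_pattern(m)$n_fixed >= 4, motifs)
    hits <- align_motifs_to_proteome(motifs, pp$proteome)
    fr <- tile_fragments(pp$proteome)
    subjects <- c("S1", "S2", "S3")
    pats <- vapply(motifs, function(m) parse_pattern(m)$string, "")
    ab <- matrix(rpois(length(pats) * 3, 50), nrow = length(pats),
                 dimnames = list(pats, subjects))
    lm <- fragment_alignment_load(hits, fr, ab)
    for (fi in seq_len(nrow(fr))) {
      inside <- hits$accession == fr$accession[fi] &
        hits$offset >= fr$start[fi] & hits$span_end <= fr$end[fi]
      ms <- unique(hits$pattern[inside])
      for (s in subjects) {
        expected <- if (length(ms)) sum(ab[ms, s]) / length(ms) else 0
        expect_equal(unname(lm$per_subject[fi, s]), expected)
      }
    }
    expect_equal(unname(lm$total), unname(rowSums(lm$per_subject)))

    # scale equivariance: doubling abundances doubles every load
    lm2 <- fragment_alignment_load(hits, fr, ab * 2)
    expect_equal(lm2$per_subject, lm$per_subject * 2)
  })
})

test_that("overlapping selected fragments merge into a 30-aa fragment", {
  prot <- c(p1 = paste(rep("A", 140), collapse = ""))
  fr <- tile_fragments(prot)
  # m1 in [100,120) and [110,130); m2 in [110,130) and [120,140):
  # loads 80, 60, 40 -> the top two overlap by 10 and merge to [100,130)
  hits <- data.frame(pattern = c("m1", "m2"), accession = "p1",
                     offset = c(112L, 122L), span_end = c(118L, 128L))
  ab <- matrix(c(80, 40), nrow = 2, dimnames = list(c("m1", "m2"), "S1"))
  lm <- fragment_alignment_load(hits, fr, ab)
  expect_equal(unname(lm$total["p1:100-120"]), 80)
  expect_equal(unname(lm$total["p1:110-130"]), 60)
  top <- select_top_fragments(lm, hits, ab, k = 5)
  merged <- top[is.na(top$frameshift), ]
  expect_equal(nrow(merged), 1L)
  expect_equal(c(merged$start, merged$end), c(100L, 130L))
  # merged load recomputed over the union span: both motifs inside
  expect_equal(merged$total_load, (80 + 40) / 2)
  # k larger than fragment count returns everything with positive load
  expect_lte(nrow(top), 5L)
})

test_that("target-type clustering applies uniqueness and size rules", {
  # 12 unique substrings within Hamming 2 of a core 12-mer: one type
  core <- "PADTAPRAGTLD"
  vary <- function(s, i, ch) { substr(s, i, i) <- ch; s }
  members <- c(core, vapply(1:11, function(i)
    vary(core, i, if (substr(core, i, i) == "A") "G" else "A"), ""))
  prot <- c(p1 = paste(c(rep("W", 4), strsplit(core, "")[[1]], rep("W", 4)),
                       collapse = ""))
  # synthesise hits/fragments around each member by planting them in a protein
  seqs <- paste0(strrep("W", 4), members, strrep("W", 4))
  prots <- setNames(seqs, sprintf("p%d", seq_along(seqs)))
  frs <- tile_fragments(prots)
  hits <- data.frame(pattern = "P..TA.R", accession = names(prots),
                     offset = 4L, span_end = 11L)
  tt <- cluster_target_types(frs, hits, prots, min_cluster = 10,
                             distance_cutoff = 9)
  expect_equal(length(tt), 1L)
  # the centred 12-mer window covers member positions 1-10 plus two W
  # flanks, so the position-11 variant collapses with the core: 11 unique
  expect_equal(tt[[1]]$n_members, 11L)
  expect_equal(colSums(tt[[1]]$pwm), rep(1, 12))
  # every position is conserved in >= 10/11 members: all fixed
  expect_equal(tt[[1]]$consensus, "WWPADTAPRAGT")

  # 15 copies of one substring + 1 distant: uniqueness means cluster of 1,
  # below the minimum -> discarded
  prots2 <- setNames(rep(paste0(strrep("W", 4), core, strrep("W", 4)), 15),
                     sprintf("q%d", 1:15))
  prots2 <- c(prots2, far = paste0(strrep("C", 4), strrep("CEH", 4), strrep("C", 4)))
  frs2 <- tile_fragments(prots2)
  hits2 <- data.frame(pattern = "P..TA.R", accession = sprintf("q%d", 1:15),
                      offset = 4L, span_end = 11L)
  tt2 <- cluster_target_types(frs2, hits2, prots2, min_cluster = 10,
                              distance_cutoff = 9)
  expect_equal(length(tt2), 0L)
})
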