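test_that("TopPeptide selection applies both presence and count thresholds", {
  ids <- sprintf("S%02d", 1:10)
  counts <- data.frame(subject_id = "S01", peptide = "ACDEFGHIKLMN", count = 12)
  counts <- rbind(counts,
                  data.frame(subject_id = c("S01", "S02"),
                             peptide = "MNPQRSTVWYAC", count = 9))
  co <- new_cohort(counts, toy_subjects(ids, perio = "P"))
  # in 1/10 subjects (= the 10% ceiling) with count 12 >= 10: included
  # in 2/10 subjects but max count 9 < 10: excluded
  expect_equal(select_group_peptides(co, "P"), "ACDEFGHIKLMN")
  expect_error(select_group_peptides(co, "X"), "unknown clinical group")
})

test_that("TopPeptide selection of an empty group count table is empty", {
  ids <- c("S1", "S2")
  sub <- toy_subjects(ids, cad = c("noCAD", "ACS"), perio = "H")
  counts <- data.frame(subject_id = "S1", peptide = "ACDEFGHIKLMN", count = 20)
  co <- new_cohort(counts, sub)
  expect_equal(select_group_peptides(co, "ACS"), character(0))
})

test_that("hypergeometric tail matches exact enumeration and edge cases", {
  expect_equal(hypergeometric_enrichment(0, 5, 10, 20), 1.0)
  expect_equal(hypergeometric_enrichment(5, 5, 10, 20), 3003 / 184756,
               tolerance = 1e-12)
  expect_error(hypergeometric_enrichment(6, 5, 10, 20), "inconsistent")
  withr::with_seed(4, {
    for (i in 1:200) {
      N <- sample(2:30, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
      k <- sample(0:min(K, n), 1)
      expect_equal(hypergeometric_enrichment(k, K, n, N),
                   hyper_tail_oracle(k, K, n, N), tolerance = 1e-12)
    }
  })
})

test_that("motif discovery recovers a planted pattern", {
  withr::with_seed(101, {
    sets <- planted_peptide_sets("P..T.PR", q_frac = 0.10)
    m <- discover_motifs(sets$query, sets$reference)
    expect_gt(nrow(m), 0)
    carriers <- sets$query[sets$query_carrier]
    hit <- vapply(m$pattern, function(p)
      mean(pattern_occurs(p, carriers)), numeric(1))
    expect_true(any(hit >= 0.9 & m$p_hyper < 1e-5))
  })
})

test_that("identical query and reference yield no enrichment", {
  withr::with_seed(7, {
    peps <- replicate(300, random_aa_string(12))
    m <- discover_motifs(peps, peps)
    expect_equal(nrow(m), 0L)
  })
})

test_that("emitted motifs always have >= 4 fixed positions", {
  withr::with_seed(19, {
    # plant a highly enriched 3-fixed pattern; it must never be emitted
    p3 <- parse_pattern("W.W..W")
    q <- c(vapply(1:300, function(i)
      mimovar:::instantiate_pattern_peptide(p3), character(1)),
      replicate(300, random_aa_string(12)))
    r <- replicate(600, random_aa_string(12))
    m <- discover_motifs(q, r)
    expect_true(all(m$n_fixed >= 4))
  })
})

test_that("motif discovery is invariant to input permutation", {
  withr::with_seed(23, {
    sets <- planted_peptide_sets("K.ST.K", n_query = 400, n_ref = 400,
                                 q_frac = 0.15, r_frac = 0)
    m1 <- discover_motifs(sets$query, sets$reference)
    m2 <- discover_motifs(sample(sets$query), sample(sets$reference))
    expect_identical(m1, m2)
  })
})

test_that("iterative exclusion removes covered peptides between runs", {
  withr::with_seed(29, {
    q <- c(vapply(1:80, function(i)
            mimovar:::instantiate_pattern_peptide(parse_pattern("P..T.PR")),
            character(1)),
           vapply(1:80, function(i)
            mimovar:::instantiate_pattern_peptide(parse_pattern("KW.EF.K")),
            character(1)),
           replicate(400, random_aa_string(12)))
    r <- replicate(500, random_aa_string(12))
    m <- discover_motifs(q, r, n_iterations = 2)
    if (max(m$iteration) > 1) {
      cov1 <- unique(unlist(lapply(m$pattern[m$iteration == 1],
                                   function(p) q[pattern_occurs(p, q)])))
      cov2 <- unique(unlist(lapply(m$pattern[m$iteration == 2],
                                   function(p) q[pattern_occurs(p, q)])))
      # iteration-2 motifs were discovered on peptides outside cov1; their
      # query coverage was counted there
      for (pat in m$pattern[m$iteration == 2]) {
        n_new <- sum(pattern_occurs(pat, setdiff(q, cov1)))
        expect_equal(n_new,
                     m$query_coverage[m$iteration == 2 & m$pattern == pat])
      }
      expect_gt(length(cov2), 0)
    }
    expect_true(TRUE)
  })
})

test_that("the strict TopMotif filter is a disjunction", {
  m <- data.frame(pattern = c("a", "b", "c"),
                  p_hyper = c(1e-9, 1e-6, 1e-6),
                  enrichment_ratio = c(2, 12, 3))
  kept <- select_top_motifs(m)
  expect_equal(kept$pattern, c("a", "b"))
})

test_that("motif abundance equals the brute-force triple loop", {
  withr::with_seed(37, {
    co <- random_cohort(n_subjects = 5, n_peptides = 40)
    motifs <- replicate(10, random_test_pattern(3, 6))
    ab <- motif_abundance(motifs, co)
    for (mi in seq_along(motifs)) {
      for (sid in co$subjects$subject_id) {
        expected <- 0
        rows <- co$counts[co$counts$subject_id == sid, ]
        for (ri in seq_len(nrow(rows))) {
          if (length(match_pattern(motifs[mi], rows$peptide[ri])) > 0)
            expected <- expected + rows$count[ri]
        }
        expect_equal(unname(ab[mi, sid]), expected)
      }
    }
  })
})

test_that("abundance of a motif matching nothing is zero everywhere", {
  co <- toy_cohort(data.frame(subject_id = c("S1", "S2"),
                              peptide = "ACDEFGHIKLMN", count = c(5, 7)))
  ab <- motif_abundance(list("WWWW"), co)
  expect_equal(unname(ab[1, ]), c(0, 0))
  ab2 <- motif_abundance(list("CDEF"), co)
  expect_equal(unname(ab2[1, ]), c(5, 7))
})

test_that("group-differential filter: separated toy passes, interleaved fails", {
  ids <- sprintf("S%d", 1:8)
  sub <- toy_subjects(ids, perio = rep(c("P", "H"), each = 4))
  ab <- matrix(c(100, 100, 100, 100, 10, 10, 10, 10), nrow = 1,
               dimnames = list("sep", ids))
  res <- select_group_differential(ab, sub, c("P", "H"))
  expect_true(res$pass_fold)              # fold 10 > 3
  expect_equal(res$best_sens, 1.0)
  expect_equal(res$best_spec, 1.0)
  expect_equal(res$p_mwu, 2 / 70)         # exact enumeration over C(8,4)
  expect_true(res$differential)

  # interleaved: huge fold via one outlier but inseparable by threshold
  ab2 <- matrix(c(1000, 2, 4, 6, 3, 5, 7, 9), nrow = 1,
                dimnames = list("mix", ids))
  res2 <- select_group_differential(ab2, sub, c("P", "H"))
  expect_true(res2$pass_fold)
  expect_false(res2$pass_sep)
  expect_false(res2$differential)

  # identical distributions are never differential
  ab3 <- matrix(rep(c(5, 9), 4), nrow = 1, dimnames = list("same", ids))
  expect_false(select_group_differential(ab3, sub, c("P", "H"))$differential)

  expect_error(select_group_differential(ab, toy_subjects("S1", perio = "P"),
                                         c("P", "H")), ">= 2 subjects")
})
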