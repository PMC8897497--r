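# Fixture builders and independent oracles shared across the test files.

# Independent regex-translation oracle for pattern matching: a pattern is
# rendered as a regular expression and matched with perl lookahead so that
# overlapping occurrences are all reported.
regex_match_oracle <- function(pattern, sequence) {
  p <- parse_pattern(pattern)
  rx <- paste(vapply(p$elements, function(e) {
    if (all(is.na(e))) "." else if (length(e) == 1L) e
    else paste0("[", paste(e, collapse = ""), "]")
  }, character(1)), collapse = "")
  m <- gregexpr(paste0("(?=", rx, ")"), sequence, perl = TRUE)[[1]]
  if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
}

# random pattern over fixed residues / classes / wildcards, trimmed form
random_test_pattern <- function(min_len = 3L, max_len = 10L) {
  len <- sample(min_len:max_len, 1L)
  kinds <- c("fixed", sample(c("fixed", "class", "wild"), max(len - 2L, 0L),
                             replace = TRUE, prob = c(0.5, 0.2, 0.3)),
             if (len > 1L) "fixed")
  paste(vapply(kinds, function(k) {
    switch(k,
           fixed = sample(AA_ALPHABET, 1L),
           class = paste0("[", paste(sort(sample(AA_ALPHABET, 2L)),
                                     collapse = ""), "]"),
           wild = ".")
  }, character(1)), collapse = "")
}

random_aa_string <- function(len) {
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

# minimal valid subject metadata
toy_subjects <- function(ids, cad = "noCAD", perio = "H") {
  data.frame(subject_id = ids,
             cad_group = rep_len(cad, length(ids)),
             perio_group = rep_len(perio, length(ids)),
             smoking = "never", diabetes = FALSE, age = 60, sex = "F",
             ebv_ca_seropositive = TRUE, stringsAsFactors = FALSE)
}

toy_cohort <- function(counts, cad = "noCAD", perio = "H") {
  ids <- unique(counts$subject_id)
  new_cohort(counts, toy_subjects(ids, cad, perio))
}

# random well-formed cohort for round-trip checks
random_cohort <- function(n_subjects = 3L, n_peptides = 8L) {
  ids <- sprintf("S%02d", seq_len(n_subjects))
  peps <- replicate(n_peptides, random_aa_string(12L))
  rows <- expand.grid(subject_id = ids, peptide = peps,
                      stringsAsFactors = FALSE)
  rows <- rows[runif(nrow(rows)) < 0.7, ]
  rows$count <- rpois(nrow(rows), 20)
  sub <- toy_subjects(ids,
                      cad = sample(c("noCAD", "sCAD", "ACS"), n_subjects,
                                   replace = TRUE),
                      perio = sample(c("H", "G", "P"), n_subjects,
                                     replace = TRUE))
  new_cohort(rows, sub)
}

# query/reference peptide sets with a planted pattern in the query
planted_peptide_sets <- function(pattern, n_query = 2000L, n_ref = 2000L,
                                 q_frac = 0.08, r_frac = 0.005) {
  p <- parse_pattern(pattern)
  gen <- function(n, frac) {
    carrier <- runif(n) < frac
    peps <- character(n)
    for (i in seq_len(n)) {
      peps[i] <- if (carrier[i])
        mimovar:::instantiate_pattern_peptide(p) else random_aa_string(12L)
    }
    list(peptides = peps, carrier = carrier)
  }
  q <- gen(n_query, q_frac); r <- gen(n_ref, r_frac)
  list(query = q$peptides, query_carrier = q$carrier,
       reference = r$peptides)
}

# exact hypergeometric upper tail by direct enumeration with binomial
# coefficients (exact in double precision for N <= 30)
hyper_tail_oracle <- function(k, K, n, N) {
  i <- k:min(K, n)
  if (length(i) == 0L || k > min(K, n)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}
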