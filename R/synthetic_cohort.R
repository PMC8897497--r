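#' @importFrom stats rlnorm rpois rbinom runif rnorm
NULL

#' Specify a planted motif effect
#'
#' Describes how a ground-truth motif is embedded in a synthetic cohort:
#' in which clinical groups it appears, what fraction of a carrier
#' subject's peptides contain it, and how strongly responder subjects'
#' counts are boosted.
#'
#' @param pattern pattern string (see [parse_pattern()]), e.g. `"P..T.PR"`.
#' @param carrier_fraction named numeric vector, clinical group label ->
#'   fraction in \[0, 1\] of that group's subjects' peptides that carry the
#'   pattern. Groups may be CAD labels (noCAD/sCAD/ACS) or periodontal
#'   labels (H/G/P); unnamed groups get 0.
#' @param boost multiplicative count boost (>= 1) applied in responder
#'   subjects of carrier groups.
#' @param responder_fraction fraction of carrier-group subjects that are
#'   responders (carry the boosted counts).
#' @return object of class `mva_plant`.
#' @export
plant_spec <- function(pattern, carrier_fraction, boost = 10,
                       responder_fraction = 1) {
  p <- parse_pattern(pattern)
  stopifnot(is.numeric(carrier_fraction), !is.null(names(carrier_fraction)),
            all(carrier_fraction >= 0), boost >= 1,
            responder_fraction >= 0, responder_fraction <= 1)
  if (any(carrier_fraction > 1)) stop("carrier_fraction must be <= 1")
  if (!any(carrier_fraction > 0)) stop("at least one group fraction must be > 0")
  ok <- names(carrier_fraction) %in% c(CAD_GROUPS, PERIO_GROUPS)
  if (!all(ok)) stop("unknown group label: ",
                     paste(names(carrier_fraction)[!ok], collapse = ", "))
  structure(list(pattern = p, carrier_fraction = carrier_fraction,
                 boost = boost, responder_fraction = responder_fraction),
            class = "mva_plant")
}

#' Default cohort design
#'
#' The study design this generator emulates: 96 subjects in a 3 CAD x 3
#' periodontal layout with 32 subjects per CAD arm, each split 7 H / 9 G /
#' 16 P.
#'
#' @param n_per_cell 3 x 3 integer matrix (rows noCAD/sCAD/ACS, columns
#'   H/G/P) of subjects per cell; the default mirrors the 96-subject
#'   clinical layout.
#' @param library_size distinct peptides observed per subject. Deep
#'   immunoprofiling yields on the order of 1e5 distinct peptides per
#'   sample; scale down for quick simulations.
#' @param shared_fraction fraction of each subject's background peptides
#'   drawn from a pool common to all subjects (shared reactivities).
#' @param count_meanlog,count_sdlog log-normal parameters of the latent
#'   per-peptide abundance; observed counts are Poisson around the latent
#'   value, giving the heavy-tailed count distributions characteristic of
#'   phage-display sequencing.
#' @return list of design parameters.
#' @export
cohort_design <- function(n_per_cell = matrix(rep(c(7L, 9L, 16L), each = 3L),
                                              nrow = 3,
                                              dimnames = list(CAD_GROUPS, PERIO_GROUPS)),
                          library_size = 1e5,
                          shared_fraction = 0.3,
                          count_meanlog = 1.5,
                          count_sdlog = 1.2) {
  n_per_cell <- as.matrix(n_per_cell)
  if (!all(dim(n_per_cell) == c(3L, 3L)))
    stop("n_per_cell must be a 3x3 matrix covering the CAD x perio design")
  dimnames(n_per_cell) <- list(CAD_GROUPS, PERIO_GROUPS)
  stopifnot(all(n_per_cell >= 0), library_size >= 1,
            shared_fraction >= 0, shared_fraction <= 1)
  list(n_per_cell = n_per_cell, library_size = as.integer(library_size),
       shared_fraction = shared_fraction,
       count_meanlog = count_meanlog, count_sdlog = count_sdlog)
}

random_peptides <- function(n, width = 12L) {
  if (n <= 0L) return(character(0))
  m <- matrix(sample(AA_ALPHABET, n * width, replace = TRUE), nrow = n)
  apply(m, 1L, paste, collapse = "")
}

# Instantiate a wildcard pattern inside a fresh random 12-mer at a random
# offset; wildcard/class positions are drawn randomly (class members for
# classes, any residue for wildcards).
instantiate_pattern_peptide <- function(p, width = 12L) {
  stopifnot(p$length <= width)
  off <- sample.int(width - p$length + 1L, 1L)
  pep <- sample(AA_ALPHABET, width, replace = TRUE)
  for (i in seq_len(p$length)) {
    e <- p$elements[[i]]
    if (!all(is.na(e))) pep[off + i - 1L] <- if (length(e) == 1L) e else sample(e, 1L)
  }
  paste(pep, collapse = "")
}

instantiate_pattern <- function(p) {
  paste(vapply(p$elements, function(e) {
    if (all(is.na(e))) sample(AA_ALPHABET, 1L)
    else if (length(e) == 1L) e
    else sample(e, 1L)
  }, character(1)), collapse = "")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Background peptides are drawn uniformly over the 12-mer space with
#' log-normal latent abundances and Poisson-distributed observed counts;
#' a configurable fraction of each subject's peptides comes from a pool
#' shared across all subjects. Planted motifs (see [plant_spec()]) are
#' embedded at random offsets in the stated fraction of carrier-group
#' subjects' peptides, with boosted counts in responder subjects. The
#' returned truth record is sufficient to score recovery by every
#' downstream stage.
#'
#' @param design see [cohort_design()].
#' @param plants list of [plant_spec()] objects (may be empty).
#' @param seed integer seed; the output is a pure function of
#'   (design, plants, seed).
#' @return list with `cohort` (`mva_cohort`) and `truth` (list:
#'   `plants`, `responders` logical matrix subject x plant,
#'   `planted_peptides` data.frame subject_id/peptide/plant).
#' @export
generate_cohort <- function(design = cohort_design(), plants = list(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  for (pl in plants) stopifnot(inherits(pl, "mva_plant"))
  withr::with_seed(seed, {
    subjects <- make_subject_table(design$n_per_cell)
    n_sub <- nrow(subjects)
    lib <- design$library_size
    n_shared <- round(design$shared_fraction * lib)
    shared_peps <- random_peptides(n_shared)
    shared_lambda <- rlnorm(n_shared, design$count_meanlog, design$count_sdlog)

    responders <- matrix(FALSE, n_sub, length(plants),
                         dimnames = list(subjects$subject_id, NULL))
    if (length(plants)) {
      for (j in seq_along(plants)) {
        pl <- plants[[j]]
        in_carrier <- subjects$cad_group %in% names(pl$carrier_fraction)[pl$carrier_fraction > 0] |
          subjects$perio_group %in% names(pl$carrier_fraction)[pl$carrier_fraction > 0]
        responders[, j] <- in_carrier &
          (runif(n_sub) < pl$responder_fraction)
      }
    }

    count_rows <- vector("list", n_sub)
    planted_rows <- list()
    for (s in seq_len(n_sub)) {
      sid <- subjects$subject_id[s]
      n_priv <- lib - n_shared
      priv_peps <- random_peptides(n_priv)
      priv_lambda <- rlnorm(n_priv, design$count_meanlog, design$count_sdlog)
      peps <- c(shared_peps, priv_peps)
      lambda <- c(shared_lambda, priv_lambda)

      if (length(plants)) {
        for (j in seq_along(plants)) {
          pl <- plants[[j]]
          frac <- max(pl$carrier_fraction[subjects$cad_group[s]],
                      pl$carrier_fraction[subjects$perio_group[s]], 0,
                      na.rm = TRUE)
          if (frac <= 0) next
          n_plant <- rbinom(1L, lib, frac)
          if (n_plant == 0L) next
          ppeps <- vapply(seq_len(n_plant), function(i)
            instantiate_pattern_peptide(pl$pattern), character(1))
          plam <- rlnorm(n_plant, design$count_meanlog, design$count_sdlog)
          if (responders[s, j]) plam <- plam * pl$boost
          peps <- c(peps, ppeps)
          lambda <- c(lambda, plam)
          planted_rows[[length(planted_rows) + 1L]] <-
            data.frame(subject_id = sid, peptide = ppeps, plant = j,
                       stringsAsFactors = FALSE)
        }
      }

      cnt <- rpois(length(peps), lambda)
      keep <- cnt > 0L & !duplicated(peps)
      count_rows[[s]] <- data.frame(subject_id = sid, peptide = peps[keep],
                                    count = cnt[keep], stringsAsFactors = FALSE)
    }
    counts <- do.call(rbind, count_rows)
    cohort <- new_cohort(counts, subjects)
    truth <- list(
      plants = plants, responders = responders,
      planted_peptides = if (length(planted_rows))
        do.call(rbind, planted_rows)
      else data.frame(subject_id = character(0), peptide = character(0),
                      plant = integer(0))
    )
    list(cohort = cohort, truth = truth)
  })
}

make_subject_table <- function(n_per_cell) {
  rows <- list()
  for (cad in CAD_GROUPS) for (perio in PERIO_GROUPS) {
    n <- n_per_cell[cad, perio]
    if (n > 0)
      rows[[length(rows) + 1L]] <- data.frame(
        cad_group = cad, perio_group = perio,
        n = seq_len(n), stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  n_sub <- nrow(df)
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n_sub)),
    cad_group = df$cad_group,
    perio_group = df$perio_group,
    # marginals follow the cohort this emulates: 19% diabetes, ~9% EBV-CA
    # seronegative, elderly cardiology patients
    smoking = sample(SMOKING_LEVELS, n_sub, replace = TRUE,
                     prob = c(0.4, 0.3, 0.3)),
    diabetes = runif(n_sub) < 0.19,
    age = round(rnorm(n_sub, 63, 8)),
    sex = sample(c("M", "F"), n_sub, replace = TRUE, prob = c(0.65, 0.35)),
    ebv_ca_seropositive = runif(n_sub) >= 0.094,
    stringsAsFactors = FALSE
  )
}

#' Generate a random proteome with planted motif sites
#'
#' Proteins are i.i.d. uniform residue sequences. Requested sites are
#' overwritten with a fresh instantiation of their pattern (wildcards
#' drawn randomly); a site with `start = NA` is placed uniformly at
#' random, re-drawn on collision with a previously placed site (error
#' after 100 attempts). A designated target protein carries one planted
#' epitope sequence in its C-terminal third, emulating a viral capsid
#' antigen whose mapped epitope sits near the C terminus.
#'
#' @param n_proteins number of background proteins.
#' @param length_range integer vector of length 2: protein lengths drawn
#'   uniformly in this range.
#' @param sites optional data.frame with columns `accession` (`"p<i>"`
#'   or the target accession), `start` (0-based, or NA for random) and
#'   `pattern` (pattern string).
#' @param target optional list: `accession` (default "TARGET"), `length`
#'   (default 176) and `epitope` (an amino-acid string planted verbatim,
#'   default `"TLPMDTSPRAHW"`). Set `target = NULL` to skip.
#' @param seed integer seed.
#' @return list with `proteome` (`mva_proteome`) and `truth` (list:
#'   `planted_sites` data.frame accession/start/pattern/instance, and
#'   `target_epitope` = accession/start/end of the planted epitope).
#' @export
plant_proteome <- function(n_proteins = 50, length_range = c(200L, 500L),
                           sites = NULL,
                           target = list(accession = "TARGET", length = 176L,
                                         epitope = "TLPMDTSPRAHW"),
                           seed) {
  if (missing(seed)) stop("seed is mandatory")
  withr::with_seed(seed, {
    lens <- sample(length_range[1L]:length_range[2L], n_proteins, replace = TRUE)
    prots <- lapply(lens, function(L) sample(AA_ALPHABET, L, replace = TRUE))
    names(prots) <- sprintf("p%d", seq_len(n_proteins))

    target_truth <- NULL
    if (!is.null(target)) {
      tl <- target$length
      tp <- sample(AA_ALPHABET, tl, replace = TRUE)
      epi <- strsplit(target$epitope, "", fixed = TRUE)[[1]]
      lo <- ceiling(2 * tl / 3)                     # C-terminal third
      start <- sample(lo:(tl - length(epi)), 1L)    # 1-based
      tp[start:(start + length(epi) - 1L)] <- epi
      prots[[target$accession]] <- tp
      target_truth <- list(accession = target$accession,
                           start = start - 1L,
                           end = start - 1L + length(epi))
    }

    placed <- list()  # per accession: matrix of occupied [start,end) 0-based
    site_rows <- list()
    if (!is.null(sites)) {
      for (i in seq_len(nrow(sites))) {
        acc <- as.character(sites$accession[i])
        if (!acc %in% names(prots)) stop("unknown accession '", acc, "'")
        p <- parse_pattern(as.character(sites$pattern[i]))
        L <- length(prots[[acc]])
        inst <- instantiate_pattern(p)
        s0 <- sites$start[i]
        if (is.na(s0)) {
          for (attempt in seq_len(100L)) {
            s0 <- sample.int(L - p$length + 1L, 1L) - 1L
            if (!overlaps_any(placed[[acc]], s0, s0 + p$length)) break
            s0 <- NA
          }
          if (is.na(s0)) stop("could not place site after 100 attempts")
        } else {
          if (s0 < 0 || s0 + p$length > L)
            stop("site outside protein bounds: ", acc, " start ", s0)
        }
        prots[[acc]][(s0 + 1L):(s0 + p$length)] <-
          strsplit(inst, "", fixed = TRUE)[[1]]
        placed[[acc]] <- rbind(placed[[acc]], c(s0, s0 + p$length))
        site_rows[[length(site_rows) + 1L]] <-
          data.frame(accession = acc, start = s0, pattern = p$string,
                     instance = inst, stringsAsFactors = FALSE)
      }
    }
    proteome <- structure(vapply(prots, paste, character(1), collapse = ""),
                          class = "mva_proteome")
    truth <- list(
      planted_sites = if (length(site_rows)) do.call(rbind, site_rows)
        else data.frame(accession = character(0), start = integer(0),
                        pattern = character(0), instance = character(0)),
      target_epitope = target_truth
    )
    list(proteome = proteome, truth = truth)
  })
}

overlaps_any <- function(occupied, s, e) {
  if (is.null(occupied)) return(FALSE)
  any(s < occupied[, 2] & occupied[, 1] < e)
}

#' Scramble peptides residue-wise
#'
#' Each output peptide is a uniform random permutation of the
#' corresponding input's residues, preserving its residue multiset — the
#' composition-matched null used for signal-to-random profiles.
#'
#' @param peptides character vector of peptides.
#' @param seed integer seed.
#' @return character vector, same length and residue multisets.
#' @export
scramble_peptides <- function(peptides, seed) {
  if (missing(seed)) stop("seed is mandatory")
  withr::with_seed(seed, {
    vapply(peptides, function(p) {
      ch <- strsplit(p, "", fixed = TRUE)[[1]]
      paste(sample(ch), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
}

#' Simulate a pair of technical replicates
#'
#' Two Poisson observations of one log-normal latent peptide profile,
#' emulating repeated sequencing of the same immunoprecipitation.
#'
#' @param n_peptides number of distinct peptides in the latent profile.
#' @param total_reads approximate library size (total read count) per
#'   replicate.
#' @param sdlog log-normal spread of the latent profile.
#' @param seed integer seed.
#' @return list of two named count vectors (`a`, `b`).
#' @export
simulate_technical_replicates <- function(n_peptides = 2e4, total_reads = 1e5,
                                          sdlog = 3, seed) {
  if (missing(seed)) stop("seed is mandatory")
  withr::with_seed(seed, {
    peps <- random_peptides(n_peptides)
    lam <- rlnorm(n_peptides, 0, sdlog)
    lam <- lam / sum(lam) * total_reads
    a <- rpois(n_peptides, lam); b <- rpois(n_peptides, lam)
    names(a) <- names(b) <- peps
    list(a = a[a > 0], b = b[b > 0])
  })
}

#' Generate epitope-level features with planted clinical effects
#'
#' Bypasses the peptide level and simulates per-subject abundances of the
#' five epitope groups (A-E) directly, with multiplicative group effects
#' whose sign structure mirrors the biomarker setting this package
#' models: epitopes A and B elevated in periodontitis, C in periodontally
#' healthy subjects; within periodontitis, A and E elevated in no-CAD;
#' within gingivitis, A elevated in ACS; within healthy, C elevated in
#' ACS.
#'
#' @param n_per_cell 3 x 3 design matrix as in [cohort_design()].
#' @param effects list of effects, each `list(epitope =, perio =, cad =,
#'   fold =)` (either of `perio`/`cad` may be NULL for "any"); the default
#'   encodes the sign structure above.
#' @param baseline_meanlog,baseline_sdlog log-normal background abundance.
#' @param seed integer seed.
#' @return list with `subjects` (metadata data.frame), `features`
#'   (subjects x epitopes abundance matrix, columns A-E) and `effects`.
#' @export
generate_epitope_cohort <- function(n_per_cell = cohort_design()$n_per_cell,
                                    effects = default_epitope_effects(),
                                    baseline_meanlog = log(100),
                                    baseline_sdlog = 0.5,
                                    seed) {
  if (missing(seed)) stop("seed is mandatory")
  withr::with_seed(seed, {
    subjects <- make_subject_table(n_per_cell)
    epis <- c("A", "B", "C", "D", "E")
    f <- matrix(rlnorm(nrow(subjects) * length(epis),
                       baseline_meanlog, baseline_sdlog),
                nrow = nrow(subjects),
                dimnames = list(subjects$subject_id, epis))
    for (ef in effects) {
      sel <- rep(TRUE, nrow(subjects))
      if (!is.null(ef$perio)) sel <- sel & subjects$perio_group == ef$perio
      if (!is.null(ef$cad)) sel <- sel & subjects$cad_group == ef$cad
      f[sel, ef$epitope] <- f[sel, ef$epitope] * ef$fold
    }
    list(subjects = subjects, features = f, effects = effects)
  })
}

#' @rdname generate_epitope_cohort
#' @export
default_epitope_effects <- function() {
  list(
    list(epitope = "A", perio = "P", cad = NULL,     fold = 8),
    list(epitope = "B", perio = "P", cad = NULL,     fold = 6),
    list(epitope = "C", perio = "H", cad = NULL,     fold = 6),
    list(epitope = "A", perio = "P", cad = "noCAD",  fold = 6),
    list(epitope = "E", perio = "P", cad = "noCAD",  fold = 6),
    list(epitope = "A", perio = "G", cad = "ACS",    fold = 6),
    list(epitope = "C", perio = "H", cad = "ACS",    fold = 6)
  )
}
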