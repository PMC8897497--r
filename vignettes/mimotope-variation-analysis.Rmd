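---
title: "Mimotope variation analysis: models, parameters and design choices"
author: "mimovar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mimotope variation analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimovar)
```

# The analysis problem

Mimotope variation analysis (MVA) sequences the random 12-mer
phage-display peptides captured by a serum sample's IgG. The raw datum
is a sparse, heavy-tailed count table: per subject, on the order of
10^5 distinct peptides with read counts spanning several orders of
magnitude. Peptides bound by the same antibody clone share short
sequence features — mimotopes of the underlying epitope — so the
analytical task is to compress millions of peptides into a small set of
wildcard sequence motifs, locate the antigens they mimic, and use
per-subject motif abundances as quantitative immune-response features.

`mimovar` implements that workflow as composable, seeded, deterministic
functions: cohort I/O and QC, motif discovery, group-differential
selection, proteome fragment scoring, epitope clustering, antigen
profiling, and a two-step clinical classifier. This vignette explains
the models behind each stage, the parameters that matter, and the
places where the design was genuinely open.

# Data model and quality control

A cohort (`mva_cohort`) couples a `(subject, peptide, count)` table
with per-subject clinical labels: CAD status (no-CAD, s-CAD, ACS),
periodontal status (H, G, P), smoking, diabetes, age, sex and EBV-CA
serostatus. Validation is total: peptides must be 12-mers over the
20-letter alphabet, counts non-negative integers, (subject, peptide)
pairs unique, and every counted subject present in the metadata —
malformed rows raise errors naming the row rather than being coerced.
Counts are kept raw (sequence reads): the selection thresholds
downstream are defined on raw counts, so no library-size normalisation
is applied anywhere in the pipeline.

Technical reproducibility is summarised by `replicate_correlation()`:
Pearson R of two replicate profiles on the `log10(count + 1)` scale
over the union of their peptides, a peptide absent from one replicate
counting 0. The log scale matches the heavy-tailed counts; the +1
pseudocount keeps absences finite. Deep MVA replicates typically
correlate at R ≈ 0.85–0.9.

# Motif discovery

## Search model

A motif (`mva_pattern`) is an ordered list of elements — fixed residue,
residue class (e.g. `[ST]`), or single-position wildcard — whose first
and last elements are fixed (trimmed form), printed as e.g. `P..T.PR`.
`discover_motifs()` explores the pattern space as a trie: patterns grow
to the right by one fixed residue or one wildcard, starting from each
single residue. Query coverage (distinct query peptides containing the
pattern) is anti-monotone under extension, which licenses pruning every
node whose coverage drops below `min_query_coverage` (default 4
peptides). The search is exhaustive over the pruned space, so results
are independent of peptide input order (enforced by sorting inputs and
asserting the anti-monotone bound during expansion).

The search alphabet deliberately excludes residue classes: classes
explode the trie combinatorially, and in practice the printed classes
of published motifs arise from position-weight-matrix consensus over
clustered sequences, which is exactly where this package produces them
(`pwm_consensus()`, `cluster_target_types()`,
`consensus_from_patterns()`).

## Scoring

A pattern matching `k` of `n` query peptides and `r` of `n_ref`
reference peptides is scored by the hypergeometric upper tail

p = P(X ≥ k), X ~ Hypergeometric(N = n + n_ref, K = k + r, n),

computed with `stats::phyper` (tested against exact rational
enumeration to 1e-12 for all margins N ≤ 30). Emission requires
`n_fixed ≥ 4` and `p < 1e-5`. Among emitted patterns with the identical
query match set, only the most specific is kept (most fixed positions,
then longest, then lexicographically first) — a deterministic
non-redundancy rule. After each iteration the covered query peptides
are removed and the search re-runs (default 2 iterations; 4 suit very
large inputs).

The reference set is the caller's choice; the natural construction used
throughout the examples is the union of the TopPeptide sets of the
other groups on the same clinical axis (e.g. P vs H ∪ G). The
query/reference enrichment ratio is `(k/n) / (max(r, 1)/n_ref)` — the
floor at one reference peptide keeps the ratio finite for reference
misses.

## Selection funnel parameters

| stage | parameter | default | rationale |
|---|---|---|---|
| TopPeptide | presence fraction | 10% of group subjects (ceiling) | shared reactivity, not private noise |
| TopPeptide | min count | 10 reads in ≥ 1 sample | above sequencing noise floor |
| search | min query coverage | 4 peptides | prune bound; smallest defensible clone size |
| search | min fixed positions | 4 | specificity of a 4-residue anchor ≈ 20⁻⁴ |
| search | p threshold | 1e-5 | discovery pass |
| search | max consecutive wildcards | 3 | bounded by the 12-mer frame |
| TopMotif | strict filter | p < 1e-8 OR ratio ≥ 10 | high significance or high effect |
| differential | fold / sens / spec / alpha | 3 / 0.5 / 0.7 / 0.05 | group-level effect plus subject-level separability plus significance |

The Mann–Whitney U test in the differential filter is exact by full
enumeration over all C(n₁+n₂, n₁) group assignments when both groups
have ≤ 8 subjects — this handles ties, which the standard exact
algorithm cannot (a perfectly separated 4-vs-4 toy gives exactly
p = 2/70) — and a tie-corrected normal approximation otherwise.

# Proteome scanning and target types

Each protein is tiled into complete 20-aa fragments in two frameshifts
(starts 0, 20, 40, … and 10, 30, 50, …). The double tiling exists to
catch motif hits straddling one tiling's boundaries, so a hit counts
toward a fragment only when its span lies fully inside it. Fragment
load for a subject is the mean abundance of the distinct motifs aligned
within it (a motif hitting twice counts once); total load sums over
subjects. The top 40 fragments per proteome are taken by total load
(ties broken by accession then start, for determinism); when two
selected fragments from different frameshifts overlap by 10 residues
they merge into one 30-aa fragment whose load is recomputed over the
union span.

For target types, the 12-mer protein substring centred on each hit
inside a top fragment (shifted inward at fragment edges; the anchoring
is not externally prescribed, so centring was chosen as the unbiased
option) is extracted; unique substrings are clustered by greedy
agglomeration joining a substring to the first cluster with a member
within Hamming distance 9 (≥ 3 identities over 12 positions — the same
identity floor as motif homology clustering), and clusters need ≥ 10
unique substrings ("no counts": multiplicity of an identical substring
does not strengthen a cluster). Each cluster is summarised by a 20×12
PWM (columns sum to 1) and a consensus string: fixed residue at
frequency ≥ 0.5, class of residues each ≥ 0.2, otherwise wildcard.

# Epitope clusters and groups

Group-differential motifs sharing ≥ 3 identical fixed residues at some
ungapped offset (gapped alignment is not attempted; motifs are short
and anchored) form single-linkage components; components with < 3
members are reported as unclustered. Cluster abundance per subject sums
the counts of peptides matched by ≥ 1 member, counting a peptide once —
summing per member would double-count the same clone.

The group × cluster matrix divides each cluster's per-group mean
abundance by its cross-group mean (rows average to 1); clusters with
cross-group mean < 150 reads are dropped as too weak to interpret.
For epitope groups, per-subject cluster abundances are log10(x + 1)
transformed (the pseudocount keeps zero-abundance subjects finite),
correlated pairwise across subjects (Pearson), and clustered with
Ward-D2 on the distance 1 − R. The tree is cut at `k` groups —
`k = 5` by default, matching the number of distinct co-response blocks
this workflow is designed to resolve, but it is an explicit parameter
because the right number is a property of the cohort, judged from the
correlation heatmap. Labels A, B, C, … are assigned in descending total
abundance for determinism. A constant abundance vector has undefined
correlation; it is assigned by the zero-correlation convention with a
warning.

# Antigen alignment profiles

`align_peptides_to_protein()` aligns each unique peptide ungapped at
every offset and counts it into the positions of its best-scoring span
when ≥ 6 of 12 residues match (all tied best offsets count once each).
Best-offset assignment avoids smearing one peptide across many weak
placements; an all-offsets mode is available via `best_only = FALSE`
since either reading is defensible. The random track aligns
residue-scrambled versions of the same peptides — a composition-matched
paired null (one scramble per peptide by default; `n_scrambles`
averages several). The per-position ratio is `(signal + 1)/(random +
1)`; the pseudocount defines behaviour where the random track is zero
and rescales ratios monotonically. `epitope_containing_abundance()`
gives the per-subject summed count of pattern-containing peptides, with
an optional threshold for a binary seropositivity call (e.g. MVA+ above
1200 reads of `P.DT.PR`-containing peptides).

# The two-step biomarker model

Features are per-subject epitope abundances, each divided by its
97.5th-percentile (linear-interpolation quantile) across subjects and
capped at 1, so a handful of extreme responders cannot dominate.

**Step 1** fits an unpenalised logistic regression ("generalised linear
model" read in its plainest form; a penalty can be added upstream by
the caller) of P vs H on epitopes A, B, C, using a stratified 80%
training split. The decision threshold is chosen to maximise balanced
accuracy of out-of-fold predictions from 5-fold CV within the training
part — the cross-validation's role is threshold selection, not model
selection, since the feature set is fixed by design. Reported metrics:
balanced accuracy on train and the held-out 20%, and training AUROC
with a seeded bootstrap 95% CI (2000 resamples by default). Complete
separation (deviance → 0 without formal convergence) is accepted as a
legitimate fit; genuine non-convergence errors with diagnostics.

**Step 2** assigns each per-periodontal-stratum marker (C in H, A in G,
A and E in P) a threshold maximising Youden's J (ties resolved toward
higher specificity), with "≥ threshold" calling the CAD group whose
marker mean is higher in that stratum. At classification time a subject
is routed by the step-1 call and judged by the assigned stratum's
rule(s); in stratum P the two markers combine by OR — either marker
above threshold suffices for the no-CAD call, reflecting that each
marks a protective response — with AND available via `combine`.

AUROC is computed by trapezoidal integration of the threshold-sweep ROC
curve; the test suite verifies it equals the normalised Mann–Whitney U
statistic exactly, including under ties.

# The synthetic cohort generator

The generator defines the conditions under which the pipeline is
validated, with full ground truth:

- **Design**: 96 subjects in a 3 CAD × 3 periodontal layout, 32 per CAD
  arm split 7 H / 9 G / 16 P — the clinical layout this workflow
  models. Marginals for smoking, diabetes (19%), sex, age and EBV-CA
  seronegativity (~9%) follow the same cohort profile.
- **Counts**: background peptides are uniform random 12-mers with
  log-normal latent abundance and Poisson observation — the simplest
  model reproducing the observed heavy tail and enabling
  technical-replicate simulation. A configurable fraction (default
  0.3) of each subject's peptides comes from a pool shared across
  subjects. The replicate simulator's latent spread (sdlog = 3) was set
  once so that two Poisson observations of one profile at 10^5 reads
  correlate at R ≈ 0.85, matching assay-typical reproducibility.
- **Plants**: a `plant_spec` embeds a pattern in a stated fraction of
  carrier-group subjects' peptides at random offsets (wildcards filled
  randomly), with counts boosted in responder subjects — responder
  structure is explicit because real cohorts show strong responses in
  subsets of a group, not uniformly. Per-peptide residue scrambling
  (not pooled) builds the null track, preserving each peptide's
  composition.
- **Proteomes**: i.i.d. uniform residue sequences with planted pattern
  instantiations at recorded sites (random placement re-draws on
  collision, erring after 100 attempts), and a target protein (default
  length 176) carrying a verbatim epitope in its C-terminal third,
  emulating a viral capsid antigen with a C-terminal mapped epitope.
- **Feature-level shortcut**: `generate_epitope_cohort()` simulates the
  five epitope abundances directly with multiplicative clinical
  effects (A and B up in P, C up in H; A and E up in no-CAD within P; A
  up in ACS within G; C up in ACS within H; folds 6–8 over a
  log-normal baseline with sdlog 0.5 — strong, clearly-separated
  planted effects), for validating the biomarker stage without the
  expensive peptide level.
- Library size defaults to 10^5 distinct peptides per subject, the
  realistic scale; validation runs use the sizes stated below.

What the generator does **not** emulate: phage-display selection
rounds, PCR/sequencing error, cross-reactive antibody families with
correlated but non-identical motifs, phylogenetic structure in
proteomes, or covariate confounding (age/sex effects on features).
Passing recovery tests therefore demonstrates correctness of the
computations and sensitivity under idealised planted signal — not
clinical performance on real cohorts, which depends on effect sizes and
noise this generator fixes by assumption.

# Validation strategy and problem sizes

The test suite validates each primitive against an independent oracle —
regex translation for pattern matching (10⁴ random pairs), exact
rational enumeration for the hypergeometric tail (all margins N ≤ 30),
brute-force loops for abundance and alignment load, the U-statistic
identity for AUROC, exact permutation enumeration for the small-sample
Mann–Whitney case — and each stage against planted truth: motif
recovery at 2000 + 2000 peptides with 8% vs 0.5% carriers (20 seeds),
top-fragment recovery on 50-protein proteomes (20 seeds),
signal-to-random calibration and epitope recovery (20 seeds each),
responder-block recovery at 20 clusters × 60 subjects (20 seeds), and
the two-step model on the 96-subject design (50 seeds, with a
shuffled-label null). These sizes were chosen to make sampling
variability negligible relative to the planted effects while keeping
the full suite fast enough to run habitually; the end-to-end pipeline
additionally runs twice on one seed and must be byte-identical.

# Known limitations

- The trie search enumerates fixed residues and wildcards only; a motif
  whose true form is a residue class at every position (no majority
  residue) would be found as several sibling patterns and only merged
  at the consensus stage.
- Homology clustering and pattern similarity are ungapped; motifs
  related by insertion/deletion are not merged.
- The greedy Hamming agglomeration of target-type substrings is
  order-dependent in principle; processing in sorted order makes it
  deterministic, but it is not a global optimum.
- Step-1 features are the epitope abundances only; clinical covariates
  are not modelled.
- Choosing `k` for epitope groups remains a judgement call on real
  data; the default is appropriate only when the correlation heatmap
  shows about five blocks.
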