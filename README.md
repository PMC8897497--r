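# mimovar

Mimotope variation analysis (MVA) of phage-display immunoprofiles in R.

MVA profiles the serum antibody repertoire by sequencing random 12-mer
phage-display peptides captured by a subject's IgG, yielding a peptide →
read-count table per subject. `mimovar` implements the downstream
computational workflow that turns such count tables into interpretable
immunology: enriched sequence motifs, proteome-level antigen maps,
epitope clusters, per-subject antigen alignment profiles, and a
two-step epitope-biomarker classifier for periodontal status and acute
coronary syndrome (ACS) risk. Because clinical immunoprofiling data are
rarely public, the package ships a synthetic-cohort generator with
recorded ground truth so every stage is testable end to end.

Intended users: computational immunologists and biomarker researchers
working with phage-display NGS readouts (or any per-sample k-mer count
data with clinical labels).

## The method

Starting from a cohort of per-subject peptide counts with clinical
labels (CAD status no-CAD / s-CAD / ACS; periodontal status H / G / P):

1. **TopPeptide selection** — a peptide is group-enriched if present in
   ≥ 10% of the group's subjects and reaching ≥ 10 reads in at least
   one of them.
2. **Motif discovery** — an exhaustive trie search over wildcard
   patterns (fixed residues and single-position wildcards, e.g.
   `P..T.PR`), pruned by the anti-monotone query-coverage bound
   (≥ 4 peptides), emitting patterns with ≥ 4 fixed positions and a
   hypergeometric enrichment *p* < 10⁻⁵ against a reference peptide
   set; covered peptides are removed and the search iterated.
   For a pattern matching *k* of *n* query peptides and *r* of the
   reference, *p* = P(X ≥ k), X ~ Hypergeometric(N = n + n_ref,
   K = k + r, n).
3. **TopMotif filter** — *p* < 10⁻⁸ **or** query/reference ratio ≥ 10.
4. **Group-differential filter** — mean abundance fold > 3 between
   contrast groups, a threshold achieving sensitivity ≥ 50% and
   specificity ≥ 70%, and a two-sided Mann–Whitney U *p* < 0.05
   (exact enumeration for small groups).
5. **Proteome scan** — motifs are aligned to bacterial proteomes
   (every fixed position must match); each protein is tiled into 20-aa
   fragments in two frameshifts (0 and −10) and scored by

   *alignment load = (sum of abundances of motifs aligned) / (count of
   motifs aligned)*;

   the top 40 fragments per proteome are selected, side-by-side
   cross-frameshift pairs merged into 30-aa fragments, and the aligned
   12-mer substrings clustered into PWM consensus "target types".
6. **Epitope clustering** — differential motifs sharing ≥ 3 identical
   fixed residues form single-linkage homology clusters (≥ 3 members);
   cluster abundances, log10-transformed, are correlated across
   subjects and united by Ward-D2 clustering into epitope groups
   A, B, C, … (descending total abundance).
7. **Antigen profiles** — per subject, unique peptides are aligned
   (≥ 6 identical positions, ungapped) along a target antigen; the same
   is done for residue-scrambled peptides, and the per-position
   signal-to-random ratio localises the epitope.
8. **Two-step biomarker model** — step 1: logistic regression of
   periodontitis (P) vs healthy (H) on the cap-normalised abundances of
   epitopes A, B, C (80/20 stratified split, 5-fold CV threshold
   selection, AUROC with bootstrap CI); step 2: per-periodontal-stratum
   Youden-optimal single-marker thresholds separating ACS from no-CAD
   (C in H, A in G, A and E in P).

## Worked example

Simulate a small cohort with a planted periodontitis-associated motif
and run the discovery funnel:

```r
library(mimovar)

design <- cohort_design(n_per_cell = matrix(2L, 3, 3), library_size = 400)
plants <- list(plant_spec("P..T.PR", c(P = 0.12, H = 0.005), boost = 15))
g <- generate_cohort(design, plants, seed = 42)
g$cohort
#> <mva_cohort> 18 subjects, 6680 (subject, peptide) count entries
#>   CAD groups:  noCAD=6 sCAD=6 ACS=6
#>   perio groups:H=6 G=6 P=6

top_p <- select_group_peptides(g$cohort, "P")   # 783 peptides
top_h <- select_group_peptides(g$cohort, "H")   # 505
top_g <- select_group_peptides(g$cohort, "G")   # 511

motifs <- discover_motifs(top_p, union(top_h, top_g))
head(motifs, 3)
#>   pattern n_fixed query_coverage ref_coverage      p_hyper enrichment_ratio
#> 1 P..T.PR       4            264           10 4.722270e-90         32.70498
#> 2 P.CT.PR       5             22            0 1.689299e-08         27.25415
#> 3 P.MT.PR       5             22            0 1.689299e-08         27.25415

strict <- select_top_motifs(motifs)             # 24 motifs survive
ab     <- motif_abundance(strict$pattern, g$cohort)
diff   <- select_group_differential(ab, g$cohort$subjects, c("P", "H"))
sum(diff$differential)
#> [1] 24
```

The planted pattern `P..T.PR` is recovered as the top motif
(*p* ≈ 5·10⁻⁹⁰, enrichment ratio 33); the more specific variants below
it are its instantiations. All 24 strict motifs pass the three
group-differential criteria for the P-vs-H contrast, as planted.

Downstream, `align_motifs_to_proteome()` + `tile_fragments()` +
`fragment_alignment_load()` + `select_top_fragments()` map the motifs
onto proteomes, `cluster_motifs_by_homology()` + `define_epitopes()`
build epitope groups, `signal_to_random_profile()` draws per-subject
antigen profiles, and `fit_two_step_model()` / `two_step_classify()`
fit and apply the biomarker model.

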