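---
title: "snordnet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{snordnet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements, the assumptions behind them, and the design decisions taken
where more than one reading was defensible. The worked numbers live in the
README and in `scripts/acceptance.R`; nothing here asserts an empirical
result that the test suite or that script does not itself compute.

## The analysis problem

Isogenic models of Prader–Willi syndrome (PWS) delete either the whole
SNHG14 transcription unit ("lgDEL") or only the SNORD116 C/D box snoRNA
cluster ("smDEL") on the paternal allele, in two genetic backgrounds (H9
and CT2 human embryonic stem cell lines), and compare induced neurons with
their unedited isogenic controls. The analysis chain this package
implements starts from differential-expression (DE) result tables and
per-window snoRNA–mRNA interaction scores — both produced by external
engines, consumed here as tables — and answers four questions:

1. Which genes are dysregulated *consistently* — across statistical
   designs, genetic backgrounds, and both deletion sizes?
2. Is the overlap between independently derived DEG lists larger than
   chance, in a direction-aware sense?
3. Do predicted snoRNA targeting events concentrate on the consistent
   genes more than on covariate-matched control genes?
4. Where do the predicted duplexes sit, on the snoRNA (relative to the
   conserved C/D′/C′/D boxes) and on the target transcript (5′UTR / CDS /
   3′UTR, exon/intron/junction)?

## Consensus differential expression

Genes are pre-filtered on the mean raw count across all samples; the two
conventional thresholds are 1 (one count per sample, used for
neuron-vs-neuron contrasts) and 39 (used where 39 samples enter an
ESC-vs-neuron contrast), both exposed as `min_mean`. Significance is
BH-adjusted p < 0.05 with strict directional rules: a gene is "up" only if
log2FC > 0, "down" only if log2FC < 0; a log2FC of exactly 0 is in neither
set, and NA adjusted p-values are never significant. Each deletion model
is tested under three designs (per-background pairwise reproducibility,
an interaction design, and a pooled condition design) and the per-model
consensus intersects all three. A flag (`require_sign_consistency`,
default TRUE) additionally requires the direction to agree across the
three designs; intersecting by identifier alone is available because the
directional requirement is the conservative reading, not the only one.
Cross-model sharing is computed in both `any_direction` and `concordant`
modes; concordant is always a subset and is the default downstream.

Foreign DE tables are trusted as-is: no re-adjustment of p-values, no
refitting. The DE engine itself is out of scope by design.

## The directional overlap permutation test

The null asks: if each side's DEG labels were assigned at random within
its tested universe, how often would the two sides share as many genes as
observed? Per replicate each universe is shuffled independently; the first
`n_up` entries are designated up and the last `n_down` down (the two
designations are disjoint by construction, and the counts match each
side's observed DEG sets); the replicate's value is
|up∩up| + |down∩down|. The implementation draws `n_up + n_down` items
without replacement and splits them head/tail, which is distributionally
identical to a full shuffle. Two p-value conventions are implemented
exactly as commonly printed: when at least one permuted value reaches the
observation, p = #{null ≥ observed}/n_perm (ties count toward p); when
none does, p is reported as the *upper bound* 1/n_perm with an explicit
`p_is_floor` flag. The enrichment value is observed/median(null); a zero
null median yields `Inf` with a `zero_null_median` flag rather than an
error, because small universes genuinely produce all-zero nulls.

Whether the shuffled list should be the full tested universe or only the
significant genes is not decidable from common usage; both are
implemented (`shuffle = "universe"` default, `"significant"` optional).
The default is the universe because designating `n_up + n_down` items
requires a superset of the significant list.

## Window merging into targeting events

Per-window scores in [0,1] arrive as a TSV whose column dialect is
configurable (`default_window_column_map()`), since window predictors do
not share a header convention; start columns are 1-based in this
package's dialect and all internal interval work uses the Bioconductor
1-based closed convention, with rtracklayer handling GTF/BED conversion
on disk. Windows qualify at score ≥ t (default 0.98) and merge when
consecutive: advancing one step (default 1 nt) on the snoRNA *and* one
step along the target mRNA simultaneously — on "−" genes the genomic
coordinate decreases as the snoRNA position advances. Equivalently, two
windows chain only if they lie on the same duplex diagonal
(target − strand·sno); this prevents unrelated duplexes between the same
snoRNA and gene from being glued together. Each *maximal* qualifying run
of length ≥ w (default 3) is exactly one targeting event — a run of five
windows is one event, not three overlapping ones — and events are counted
per snoRNA copy, with group means dividing by all copies in the group
including zero-count copies. A `max_gap` escape hatch (default 0) can
tolerate missing windows inside a run. Identical duplicate rows (the same
genomic site reached via several transcripts) are collapsed before
merging; duplicated keys with conflicting scores are an error.

## Covariate-matched control enrichment

Control lists must "look like" the query in everything except the planted
signal. Three covariates are computed per gene: exonic length (bp of the
union of exons over retained transcripts), GC over that same merged
exonic sequence, and expression (mean library-size-normalized count over
the nominated samples). Matching is by rejection sampling: draw m genes
without replacement from the universe minus the query, and accept when
two-sided Wilcoxon rank-sum tests (tie-corrected, normal approximation)
exceed α = 0.05 for all three covariates, i.e. the list does not differ
detectably from the query in any of them. The three tests are marginal,
not joint, matching how the covariates are described; lists are sampled
independently and may overlap one another. Expression is compared on the
log2(x+1) scale by default — the rank test is invariant to that monotone
transform, so this affects reporting only. If `max_iter` draws cannot
produce k acceptances the error reports the acceptance rate and which
covariates drove the rejections, which is the actionable diagnostic when
the universe is badly mismatched.

Enrichment mirrors the overlap test's conventions: for each statistic
(mean, median, sum of per-gene event counts) the observed query value is
compared with the k control-list values; fold = observed/median(null) and
p = #{null ≥ observed}/k, floored at 1/k. Using the median as the fold
reference keeps the two permutation-style tests consistent; a mean
reference is a one-line change.

## Positional profiles

Registry copies carry synthetic but structurally valid box coordinates:
the order C < D′ < C′ < D along the snoRNA is enforced, and ASE2 — the
second antisense element, the guide region that base-pairs with targets —
is defined as the segment strictly between the 3′ end of C′ and the 5′
end of the D box. Event centers (midpoint of the snoRNA-side interval,
floored at .5) divided by copy length give relative positions in [0,1];
histograms default to 0.01-wide bins, and box overlays are per-group mean
relative intervals.

Target-side coverage builds a labeled bp space per gene from retained
transcripts (TSL 1–3 with the basic tag; NA or non-numeric TSL always
fails the filter, since only levels 1–3 are named as kept): exon space is
the union of exons; intron space is the union of per-transcript introns
minus exon space (exonic precedence); exonic bp get a per-bp vote across
transcripts for 5′UTR/CDS/3′UTR (non-coding transcripts vote "other"),
with ties resolved CDS first, then 5′UTR, then 3′UTR — a deterministic
rule chosen because transcript disagreement has no canonical resolution.
Intervals classify as exon, intron, or junction (touching both), with an
explicit "unassigned" bucket for intervals outside all gene space rather
than silent dropping; exonic intervals sub-classify by the set of
subspaces they touch (5′UTR+CDS and 3′UTR+CDS composites, everything else
"other").

The metagene maps an event midpoint per matched transcript: fraction
through the 5′UTR → [0,1), through the CDS (the "gene body" of a coding
transcript) → [1,2), through the 3′UTR → [2,3); non-coding transcripts map
their whole exonic span to [1,2). With a region of length L and the
midpoint at its p-th exonic base, the coordinate is region + (p−1)/L, so
the first CDS base maps to exactly 1.0. Contributions are averaged over
all matched retained transcripts (a `--longest-transcript`-style single
representative was considered and rejected as the default because it
discards isoform information; averaging is symmetric and
strand-mirror-invariant, which the tests verify). Densities are
normalized to integrate to 1.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions. It emulates:

* a 2-background × 3-genotype × 6-replicate design (six biological
  replicates per cell, the upper end of typical inducible-neuron designs)
  with negative-binomial counts, variance = μ + αμ² with α = 0.05 and
  per-gene baseline means log-uniform on [20, 2000];
* planted truth: shared DEGs (perturbed |log2FC| = 1 in both backgrounds
  and both deletions), background-specific DEGs (one background only),
  and nulls, all recorded in a truth table;
* DE tables generated parametrically from truth: planted genes receive a
  near-zero p-value with probability `power` per design, independently;
  everything else is uniform, and BH runs over the whole table, so power
  1 guarantees significance and null false positives behave like BH on
  uniform p-values. Background-specific genes can reach significance only
  in the pooled condition-only design — a one-background effect diluted
  across backgrounds — so they cannot survive the three-design consensus.
  This is explicitly *not* an emulation of any DE engine;
* window-score tables: sub-threshold noise everywhere, plus planted runs
  of ≥ 3 consecutive windows scoring ≥ 0.98 at a Poisson base rate of 4
  events per gene, multiplied by `enrichment_fold` (2.5 in the study
  conditions) on target genes. Copy choice is biased 0.8 toward group-III
  SNORD116 copies, snoRNA position 0.8 toward ASE2, and target position
  0.8 toward 5′UTR space, with the same biases on target and non-target
  genes so only the event *rate* separates them;
* a toy annotation (1–3 transcripts per gene, 1–8 exons, mixed TSL and
  basic tags, controlled per-gene GC) and per-chromosome sequence. The
  first transcript of each gene always passes the TSL/basic filter so
  every gene remains analyzable.

What it does **not** emulate: read-level artifacts, isoform switching,
batch effects beyond the background-specific DEGs, dispersion shrinkage,
or the score distribution of any real window predictor. Passing tests
therefore demonstrate the correctness and calibration of the statistics
under NB/uniform assumptions, not performance on real sequencing data.

Unstated-by-necessity values (snoRNA copy lengths ~90–100 nt, canonical
box positions, the 13-nt window length, the window-table dialect) are
configurable placeholders chosen once to be structurally realistic; they
are documented as such and never tuned against outcomes.

## Numerical and scale choices

* Permutation nulls are seed-deterministic; every stochastic entry point
  takes a `seed` argument, and the pipeline derives per-stage seeds from
  one master seed (kept within 32-bit range).
* Degenerate inputs are flagged, not crashed on: zero null medians,
  all-zero event counts (p = 1, fold flagged undefined), zero-size
  libraries in normalization, genes with no retained transcripts
  (excluded with a warning), intervals outside gene space (an explicit
  unassigned bucket).
* Test problem sizes are chosen so each statistical claim is measured at
  the precision its tolerance needs while the whole suite stays quick:
  calibration uses universes of 4000 genes with 600 up/600 down per side
  (fine-grained null support so discrete p-values approximate the uniform
  well), 500 datasets × 500 permutations; consensus recovery uses 200
  simulated table sets; matched enrichment uses 50 seeded end-to-end runs
  with k = 100 lists; the oracle comparison covers 1000 random window
  vectors. The default pipeline run uses 800 genes.
* The acceptance script reports only quantities computed at run time by
  the installed package; all of them derive from `--seed`.

## Known limitations

* The consensus stage consumes exactly three designs per model; other
  intersection depths require composing the set operations directly.
* The per-bp majority labeling of exonic space is one defensible
  resolution of transcript disagreement; per-transcript (rather than
  union) junction classification is not offered.
* Matched lists may overlap one another, and genes inside the query locus
  are not specially excluded from the control universe; both behaviors
  are documented choices rather than claims about the only correct
  procedure.
* The interaction filter assumes a constant window length per table and
  step-1 sliding; gapped alignments of duplexes are outside its model.
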