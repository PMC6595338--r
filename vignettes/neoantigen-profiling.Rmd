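---
title: "Neoantigen profiling of somatic mutation cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neoantigen profiling of somatic mutation cohorts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoprofiler)
```

## The analysis in one paragraph

Tumor-specific mutant peptides (neoantigens) arise when a somatic missense
mutation changes a protein, the mutant protein is degraded, and one of the
resulting 8–11-residue fragments binds a class-I MHC (HLA-A/B/C) molecule
tightly enough to be presented to T cells. `neoprofiler` implements the
downstream-of-calling portion of this analysis for a patient cohort: from an
annotated somatic variant table and 4-digit HLA class-I genotypes it
enumerates candidate mutant peptides, scores peptide–allele pairs through a
pluggable binding predictor, applies IC50 thresholds to call neoantigens and
strong binders, and summarizes the cohort — substitution spectrum,
tumor mutation burden (TMB), recurrently mutated genes and their
cancer-gene-census subset, HLA carrier frequencies — together with one-sided
rank-sum comparisons of neoantigen burden across clinical subgroups. A
packaged 32-patient gastric cancer whole-exome cohort summary serves as the
reference fixture, and a seeded synthetic-cohort generator provides
full-pipeline test data.

Upstream stages — read alignment, somatic variant calling, HLA typing from
sequence, and the binding predictor's neural network itself — are out of
scope. The package starts from called, annotated variants and typed HLA,
and treats the predictor as a contract: a deterministic mock for testing
plus a loader for precomputed affinity tables produced by a real predictor.

## Peptide enumeration

For a missense variant at protein position $p$ in a protein of length $N$,
the candidate set consists of every window of length
$L \in \{8, 9, 10, 11\}$ that lies fully within the protein and covers $p$.
The number of such windows per length is

$$ \min(p,\; N - L + 1) - \max(1,\; p - L + 1) + 1 $$

when positive, so an interior mutation at least 11 residues from both
termini yields $8 + 9 + 10 + 11 = 38$ candidates. Windows truncated by a
terminus are dropped, not padded: class-I ligands are contiguous peptides
and padding has no biological meaning. Applying the substitution first and
enumerating second guarantees every candidate differs from its wild-type
window at the recorded offset. Identical peptide sequences arising from
repeats are emitted once per (peptide, mutation) pair but kept across
distinct mutations; the choice is recorded in the candidate table itself
(one row per retained pair). Indels and stop-gains are not enumerated —
they are counted in patient summaries only. The reference-residue check in
`apply_missense()` is deliberately strict: a mismatch between the variant
annotation and the supplied protein model aborts (or skips, under
`on_mismatch = "skip"`) rather than silently mutating the wrong residue.

## Binding calls and thresholds

A predictor contract maps (peptide, allele) to a predicted IC50 in nM. Two
implementations ship:

* `affinity_table_predictor()` wraps a table of precomputed affinities.
  Queries for uncovered pairs raise an error — never a silent default —
  and conflicting duplicate rows are rejected at load time. Results meant
  for interpretation must come through this route.
* `mock_predictor(seed)` is a deterministic, seeded scorer used by tests
  and simulations: per-residue weights at the two classical anchor
  positions (position 2 and the C-terminus) plus a hash-derived
  peptide–allele perturbation, mapped onto roughly 1–50,000 nM. It is
  non-biological by construction and its label says so in every output.

`call_neoantigens()` keeps pairs with IC50 $\le$ `weak_nm` and flags
`ic50 < strong_nm` as strong binders. Defaults are `weak_nm = 500` (the
conventional binder cutoff of common MHC-I predictors) and
`strong_nm = 100` (the strong-binder cutoff used in the reference study).
Both are plain arguments because conventions differ between predictor
versions. The counting unit for per-patient neoantigen burden is the
distinct (peptide, allele) pair, which is why one recurrent mutation can
contribute different counts in patients with different genotypes. Strong
calls are a subset of calls at every threshold setting, and lowering
`weak_nm` can only remove calls — both properties are tested.

## Substitution spectrum

Single-base substitutions are reported on the pyrimidine-referenced strand,
the convention under which exactly six classes exist (C>A, C>G, C>T, T>A,
T>C, T>G): a purine reference is complemented together with its alternate,
so G>T counts as C>A. Transitions are C>T and T>C. The summary is computed
over missense records that carry nucleotide annotation; indels and
protein-only records are counted in `n_skipped` so that nothing disappears
silently. No trinucleotide context is modelled — mutational-signature
decomposition is out of scope.

## Cohort summaries

TMB is missense count divided by the interrogated exome size in Mb. The
default `exome_mb = 30` is the convention under which a median of 138
missense mutations corresponds to a median TMB of 4.6 mutations/Mb, as in
the reference cohort; it is configurable because capture kits differ.
Patients with TMB above 40 mutations/Mb are flagged as hypermutators.

Gene recurrence counts *patients*, not mutations: a gene hit eight times in
one patient contributes one carrier. This is required for occurrence
percentages of the "mutated in $k$ of $n$ patients" kind. Recurrence
fractions are emitted at full precision; rounding (e.g. 9/32 = 28.125%,
printed as 28.13%) is left to the reporting layer. Census intersection
matches symbols exactly but case-insensitively. HLA carrier frequencies use
set semantics per patient, so homozygosity never double-counts; this
matches the definition of carrier frequency as the fraction of patients
carrying at least one copy.

The per-patient median reported for any count column is the standard sample
median (mean of the two central order statistics for even $n$). For the
packaged reference table this gives 138 missense, 202 neoantigens and 13
indels — the two central indel counts are 12 and 14, so summaries that
quote 14 are reporting the upper central value rather than the standard
median.

## The rank-sum convention

Subgroup comparisons use the Wilcoxon–Mann–Whitney rank-sum test in one
fixed, documented convention:

* midranks for ties;
* tie-corrected null variance
  $\sigma^2 = \dfrac{n_a n_b}{12}\left[(n+1) -
  \dfrac{\sum_t (t^3 - t)}{n(n-1)}\right]$;
* $z = (U - n_a n_b / 2)/\sigma$ with **no** continuity correction;
* one-sided normal tail per the stated alternative.

This convention was fixed because it reproduces, from the packaged
reference table, all four published subgroup p-values (0.0202 for T1a vs
T2, 0.0294 for T1a vs T4b, 0.0795 for male vs female, 0.1525 for over-45
vs under-45) to the printed precision; continuity-corrected and
exact-permutation variants do not, but both remain available via the
`continuity` and `exact` arguments. The age split is *inclusive* on the
young side (age $\le 45$): the reference cohort contains exactly four
patients aged 45 or less, matching the published group size of 4, and only
this split reproduces the published p-value.

A numerical point worth knowing: the uncorrected normal tail approximates
the permutation **mid-p** (half weight on the observed $U$), not the
inclusive exact p. On tie-free groups of 3–6 the two agree within 0.02 by
exhaustive enumeration, while the inclusive exact p — a step function with
increments as large as $1/\binom{n}{n_a}$ — can differ from the normal
tail by up to 0.17 at the smallest sizes. The property tests assert the
mid-p relationship; `exact = TRUE` returns the inclusive enumeration value.

Directions are fixed a priori (earlier stage greater, male greater, older
greater) and raw p-values are reported by default; Benjamini–Hochberg
adjustment is available via `p_adjust = "BH"` but off by default, matching
the reporting convention of the reference study. Comparisons in which a
group has fewer than two members are skipped with a warning — a two-member
group (the smallest stage in the reference cohort) is the documented
minimum. All-identical data has zero rank variance and raises an error
rather than returning a meaningless z.

The missense-versus-neoantigen relationship is summarized by an ordinary
least-squares fit; $R^2$ equals the squared Pearson correlation (0.8845 on
the reference table).

## The synthetic generator

`generate_cohort()` draws, from a single seed: random protein models
(default 2,000 genes of 100–800 residues — large enough that a
median-burden cohort leaves most genes below the recurrence threshold),
per-patient missense burden, substitution classes i.i.d. from
`spectrum_probs`, Poisson indel counts with mean `indel_rate` per missense,
independent-carrier HLA draws (resampling one allele if a patient would
otherwise carry none), and covariates. All outputs are byte-identical
across runs with one seed, and the caller's RNG stream is left untouched.

Burden is a two-component mixture. The non-hypermutator component is a
log-normal (`burden_log_mean = log(138)`, `burden_log_sd = 0.75` — the
log-scale spread of the reference cohort's non-hypermutator counts, which
range from 9 to 427 around a median of 138) *truncated above* the
hypermutator boundary (TMB 40 × 30 Mb = 1,200 missense). The hypermutator
component (probability 2/32, scale ×10) is truncated *below* the same
boundary. Truncation makes the two components disjoint by the definition
of "hypermutator": in the reference cohort the largest ordinary burden
(427) sits far below the boundary while the two hypermutators (1,336 and
1,672) sit above it, and an untruncated log-normal would occasionally leak
ordinary patients across the line, making "hypermutator" ambiguous.
Removed tail mass is well under 1% at the defaults.

Other defaults mirror the reference cohort's printed summaries: the
six-class spectrum (32.18% C>A, 27.24% C>T, 12.51% T>G, 12.29% T>C, 9.89%
C>G, 5.89% T>A), `indel_rate = 0.087` (the cohort's 658 indels per 7,594
missense), stage distribution 2/7/5/18 over T1a/T2/T4a/T4b, 11/32 female,
ages 38–80, and an allele pool led by A\*11:01 (0.469), C\*01:02 (0.375),
A\*03:01, A\*24:02 (0.25), B\*40:01 (0.219); the remaining pool entries are
set at plausible East-Asian carrier frequencies for alleles that appear in
the reference driver-mutation table. `stage_effect` is a per-stage
multiplicative neoantigen-rate factor consumed by the simulation harness,
which thins each patient's calls with retention probability proportional
to the factor; its default is constant (1 for every stage), i.e. the null,
so that the burden–neoantigen correlation check below is well defined. A
stage pattern (e.g. elevated T1a rates) is induced by setting unequal
factors.

`parameter_recovery_suite()` runs the full pipeline on a generated cohort
with the mock predictor and checks recovery: the sample median of missense
burden within three standard errors of the configured log-normal median
(SE $\approx 1.2533\,\sigma_{\log}/\sqrt{n}$ on the log scale); every
carrier frequency within $\max(3\,\mathrm{SE}_{\text{binomial}},\ 1/n)$
(the floor accounts for the at-least-one-allele guarantee, which can only
raise the rarest frequencies at small $n$); and, when `stage_effect` is
constant, $R^2 > 0.5$ for the missense-versus-neoantigen fit — the
mechanism by which mutation burden drives neoantigen burden. With 12
alleles and $n = 32$, a three-SE check on every allele fails on a few
percent of seeds by chance; that is the expected behaviour of the
tolerance, not a generator defect, and the packaged tests use fixed seeds.

### What the generator does and does not emulate

It reproduces the *summary-level* structure the analysis consumes: burden
heterogeneity with rare hypermutators, a configurable spectrum, skewed
allele frequencies, covariate distributions, and a monotone
burden-to-neoantigen mechanism. It does **not** emulate genomic
coordinates, sequence-context-dependent mutation rates, linkage between
mutations, transcript structure, real HLA linkage disequilibrium, or any
biology in the mock predictor's scores. Passing tests therefore
demonstrate that the pipeline's bookkeeping and statistics are correct
under the stated model, not that predictions on real data are accurate —
the latter depends entirely on the external predictor supplied through the
affinity-table route.

## Numerical choices and degenerate inputs

* Peptide lengths outside 8–11 are rejected unless explicitly allowed.
* Spectrum fractions over zero classifiable records are `NA`, flagged by
  `n_classified = 0`, never silently zero.
* `rank_sum_test()` errors on empty groups and on zero rank variance;
  `fit_linear()` errors on fewer than 3 points or constant x.
* HLA alleles are normalized (zero-padded, starred) before any comparison,
  so carrier counting can never split one allele across spellings.
* TNM strings parse case-insensitively ("T4Bn3aM0" → T4b) because
  published staging tables are inconsistent in case.
* All TSV output is written deterministically (no row reordering, fixed
  column order), which is what makes byte-identical reproduction possible.

## Problem sizes used by the packaged tests

The test suite runs the full recovery suite once at the study scale
(32 patients, ~5,000 missense variants, ~200,000 scored peptide–allele
pairs), spectrum recovery on cohorts of ≥5,000 classified variants,
an exhaustive window-count check for every protein length up to 50 and
every mutation position, full permutation enumeration for group sizes up
to 6, and 10,000 null simulations at $n_a = n_b = 20$ for the test-size
check. These sizes were chosen so each property is checked at the scale
where its approximation error or sampling noise is best understood.

## Known limitations

* Per-patient neoantigen counts cannot be recomputed from sequence alone:
  they depend on the external binding predictor. The packaged reference
  counts are fixture data; the statistics layer reproduces the published
  subgroup comparisons from them exactly, but the binding stage itself is
  validated by properties (determinism, monotonicity, threshold algebra),
  not by reproducing published per-patient counts.
* Peptides are deduplicated per gene; if two transcripts of one gene both
  contain the mutated window, the candidate appears once.
* The census filter is a membership test on symbols; it does not track
  census roles or synonym resolution.
* The ICGC donor counts carried in the driver-mutation fixture are
  reference data only; no external database is queried.
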