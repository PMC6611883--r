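---
title: "Methods: mutational signature extraction, refitting and diagnostics in sigcraft"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutational signature extraction, refitting and diagnostics in sigcraft}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

Every analysis in this package is organized around the factorization

$$C \approx S\,E$$

where $C$ is the **catalog matrix** (96 single-base-substitution channels
$\times$ samples, non-negative integer counts), $S$ the **signature matrix**
(96 channels $\times$ $K$ signatures, each column a probability distribution
over channels), and $E$ the **exposure matrix** ($K \times$ samples, the
number of mutations attributed to each process in each sample). The 96
channels are the six pyrimidine substitution classes (C>A, C>G, C>T, T>A,
T>C, T>G) crossed with the 16 flanking-base combinations; purine-reference
mutations are reverse-complemented before classification, so the two strand
representations of any SNV always land in the same channel.

Two families of method operate on this decomposition:

* **De novo extraction** estimates $S$ and $E$ jointly from $C$
  (non-negative matrix factorization). It can discover novel processes but
  extracted signatures are noisy and may merge or split real ones.
* **Fitting (refitting)** estimates $E$ for a fixed $S$, typically a
  published reference catalog. It quantifies known processes precisely but
  can only ever report what it was given, and without constraints it
  overfits: with a large reference, every sample tends to receive small
  spurious contributions from many signatures.

The package's recommended workflow (`run_workflow()`) therefore proceeds:
extract de novo with rank selection, assign the extracted signatures to a
reference, then refit exposures against the shortlist of assigned
signatures only, with sparse forward selection. The stages exist
separately so each can be interrogated on its own.

# De novo extraction

`nmf_decompose()` minimizes the generalized Kullback–Leibler divergence
$D(C \,\|\, SE)$ by multiplicative updates from a seeded random start;
a Frobenius objective is available behind a flag. The KL objective is the
natural choice for count data (it is the Poisson log-likelihood up to a
constant). Signature columns are renormalized to sum to one after
convergence, with the scale absorbed into $E$, so exposures are in
mutation counts.

`extract_signatures()` wraps this in a bootstrap: each of `n_bootstraps`
resampled catalogs (per-sample multinomial resampling, totals preserved)
is factorized from `n_restarts` random starts, keeping the best objective.
The pooled $K \cdot n_\text{bootstraps}$ signature vectors are partitioned
into $K$ clusters on cosine distance (deterministic assign/recenter passes
seeded from the best overall run), and the normalized cluster centroids are
the consensus signatures. **Stability** of a signature is the mean
silhouette width of its cluster; for $K = 1$ it is defined as $1$ since no
between-cluster term exists, which keeps rank-selection comparisons
well-defined. `select_rank()` recommends the largest $K$ whose mean
stability is at least 0.8 (configurable), returning the full metric table
so the user can override.

Defaults are `n_bootstraps = 100`, `n_restarts = 10`, `max_iter = 10000`,
`tol = 1e-9`. These are this package's own choices; published applications
of the framework rarely state theirs. The worked examples and tests use
reduced settings (30 bootstraps, 2–3 restarts, a few thousand iterations)
— at the cohort sizes simulated there (tens of samples, thousands of
mutations each) recovery is already at cosine > 0.9 and the reduced
settings keep examples fast; the chosen problem sizes are stated with each
example.

## Exposures reported by extraction

A deliberate design decision: `extract_signatures()` reports exposures from
the *framework's own unpenalized KL fit* of the consensus signatures to the
original catalog (`fit_exposures_kl()`), not from a non-negative
least-squares cleanup. An NMF pipeline's exposures are what a practitioner
sees first, and their failure mode is scientifically important: the
unpenalized fit spreads small positive exposures across all signatures,
which is precisely the mechanism of **inter-sample bleeding** (below). Had
extraction silently reported sparse NNLS-refit exposures, the refit stage
of the workflow would be a no-op and the bleeding diagnostic could not
demonstrate anything. `exposure_fit = "nnls"` switches behaviours.

# Fitting

`fit_exposures()` solves per-sample non-negative least squares
$\min_{e \ge 0} \lVert c - S e\rVert_2$ (Lawson–Hanson, via pracma), then
rescales so attributed mutations sum to the sample's burden.
`fit_forward_selection()` adds sparsity: starting from an empty model it
greedily adds the signature whose inclusion (with full NNLS refit of the
candidate set) most reduces the cosine reconstruction error, stops when
the best improvement falls below `stop_tol = 0.001`, then zeroes any
selected signature contributing less than `prune_threshold = 0.06` of the
sample's mutations and refits the survivors once. The 6% pruning rule is
the established minimal-contribution heuristic for sparse refitting; the
per-candidate exact NNLS refit replaces the golden-section weight search
used by some tools — deterministic and simpler, with the same intent.
Pruning is one-shot rather than iterated; iterating would only matter when
several signatures sit just below threshold simultaneously, and one-shot
behaviour is easier to reason about. Samples under 50 mutations are fitted
but flagged low-confidence; no minimum is enforced.

No trinucleotide-frequency normalization (exome/genome correction) is
applied anywhere: catalogs are assumed to come from whole genomes and the
reference signatures to be on the same footing. The hook for such a
correction is to transform the catalog before fitting.

# Assignment to a reference

`assign_to_reference()` matches each extracted signature to (i) the single
reference signature of maximal cosine similarity and (ii) the best
non-negative two-signature combination (exact NNLS per pair, weights
renormalized). Because the pair model nests the single model, the pair
cosine is never lower; the combination label "X+Y" is only reported when
it improves the single match by more than `pair_margin = 0.01` — below
that, the pair's advantage is indistinguishable from noise and the single
label is kept. Extracted signatures whose best pair similarity stays below
`novelty_threshold = 0.9` are flagged *potentially novel* and carried
as-is into the shortlist refit; the package reports the similarity and
leaves the novelty judgment to the user. Ties are broken by lexicographic
reference name, and pair members are ordered by name, so output is
invariant to reference column order.

A note on the shipped reference: no published signature catalog is bundled.
`synthetic_reference_signatures()` generates a deterministic, clearly
synthetic 30-signature stand-in (sparse Dirichlet-like profiles plus a few
deliberately flat members that mimic the mutual-substitution behaviour of
flat signatures in real catalogs). Real analyses should supply a published
catalog as TSV via `read_signature_table()`.

# Diagnostics

**Reconstruction error** (`reconstruction_error()`) is computed per sample
between the observed 96-vector and $S e$ as cosine error
($1 - $ similarity), RMSE over raw counts, or generalized KL divergence
between the normalized profiles with a $10^{-9}$ pseudocount on both sides
(zero channels are routine at low burden; the pseudocount bounds the
divergence without visibly distorting it).

**The necessity test** (`signature_necessity_test()`) asks whether a
candidate signature is *required* to explain a cohort: exposures are
fitted with and without the candidate (or with it substituted for a named
base signature), all three error metrics are compared per sample with a
two-sided paired Wilcoxon signed-rank test, and the mutations the
candidate loses are traced to the signatures that absorb them. Adding any
signature always reduces error somewhat — statistical significance alone
is therefore not evidence of activity. The package operationalizes a
*qualitative* error increase as a median relative increase above 20%
(configurable, reported alongside the raw distributions); this threshold
is this package's own, chosen so that removing a genuinely active process
(which typically multiplies the error several-fold in affected samples)
is cleanly separated from removing a redundant collinear one (a few
percent). The expected pattern for a spurious flat candidate is:
statistically significant improvement when included, no qualitative
degradation when excluded, and its mass reassigned predominantly to the
collinear flat signatures that are genuinely active.

**Exposure clustering** (`exposure_clustering()`) hierarchically clusters
samples on cosine distance between relative-exposure vectors (average
linkage), cutting at the silhouette-optimal number of clusters between 2
and min(8, n−1), falling back to a single cluster when all samples are
effectively identical. It is the unsupervised route to discovering
subgroup structure when no prior grouping (such as IGHV mutation status)
is available.

**Split extraction** (`split_extraction()`) runs extraction independently
per sample group with derived sub-seeds and cross-matches the per-group
signatures by cosine — the second cure for bleeding: a process restricted
to one group should be recovered only in that group's run.

# Localized hypermutation

`intermutation_distances()` and `detect_clusters()` implement run-based
kataegis detection: a cluster is a maximal run of at least `min_mutations`
consecutive same-chromosome mutations whose intermutation-distance
statistic is within `max_imd`. Two definitions are in circulation and both
are expressible: the default (≥ 6 consecutive mutations, **mean** IMD
≤ 1 kb) and the alternative (> 5 mutations, **median** IMD < 1 kb,
`statistic = "median", strict = TRUE`). They differ only when mean and
median straddle the ceiling; neither is silently preferred — the
parameters are echoed in output. Qualifying windows that share mutations
are merged into one maximal cluster; adjacent runs separated by a
criterion-violating gap remain distinct. Detection is the literal maximal-
window reading of the run definition rather than a segmentation of the IMD
profile; a segmentation-based detector could be slotted in behind the same
interface. Intermutation distances are computed on reference coordinates;
around complex rearrangements or VDJ joins the true genomic distances
differ from reference distances, and no correction is attempted — for
immunoglobulin work, prefer restriction to known loci (`regions()`,
`read_bed_regions()`) over distance-based detection, which is also why
`localized_analysis()` accepts either source.

`localized_analysis()` restricts mutations to detected clusters or to a
region set (e.g. IGH/IGK/IGL), builds the localized catalog, and fits with
forward selection against an extended reference that may include localized
profiles absent from genome-wide catalogs (e.g. a canonical-AID profile,
user-supplied; `caid_like_profile_synthetic()` is a clearly-labelled
synthetic stand-in for simulations only). The diagnostic signature of a
genuinely localized process is the contrast: dominant in the localized
fit, negligible — typically pruned to zero by the 6% rule — genome-wide.

# The synthetic cohort generator

The simulator exists so that every stage is testable against known truth
without controlled-access data, and its defaults define the conditions
under which the package's claims are verified:

* `generate_catalog()` draws each sample's channel counts as one
  multinomial of the sample's total from its mixture $S w$.
* `generate_positioned_cohort()` builds a toy genome (two chromosomes of
  5 Mb by default), plants Poisson background mutations with channels
  drawn from the group mixture, then plants kataegis runs with gaps drawn
  uniformly from 3 bp to the target spacing — the 3 bp floor guarantees
  planted trinucleotide contexts never overlap, so the reference can be
  edited to make every mutation's context match its drawn channel exactly
  (half the sites are planted in the purine-strand representation).
  Emitted FASTA and VCF round-trip through the package's own readers.
* `make_flat_signature_set()` constructs near-uniform profiles at a
  target pairwise cosine (±0.03) for ambiguity and collinearity studies.
* `simulate_preset()` packages four standing scenarios: `mixtures`
  (4 well-separated signatures, 50 samples × 5000 mutations),
  `kataegis` (3 planted clusters of 8 mutations per sample on an
  APOBEC-like profile over a 50 mutations/Mb background, so clusters are
  under 5% of each sample's burden), `bleeding` (below), and
  `flat-ambiguity` (two flats at cosine 0.9).

The `bleeding` preset deserves detail, since it reproduces a failure mode:
24 samples in two groups share one sharp signature and one flat signature,
and group A additionally carries a second flat signature (pairwise cosine
0.75 with the shared flat, at roughly a third of each group-A sample's
mutations; per-sample weights vary Dirichlet-style). Signature similarity is the documented driver of
bleeding, and at these settings pooled extraction recovers all three
signatures yet attributes a median of several percent of the restricted
signature to the group that lacks it, while both cures (shortlist refit
with forward selection; split extraction) reduce that median below 1%.
With a well-separated restricted signature the artifact largely vanishes
— which is itself informative, but not the regime of interest.

What the simulator does *not* emulate: real genome base composition and
regional mutation-rate covariates (replication timing, chromatin),
sequencing artifacts and caller-specific error profiles, copy number,
subclonal structure, and VDJ rearrangement geometry. Passing tests on
these cohorts demonstrates correctness of the algorithms under their
stated models, not robustness to every property of real tumor genomes.

# Numerical and degenerate-input conventions

* All randomness flows from one integer master seed through named,
  deterministically derived substreams; equal seeds give byte-identical
  outputs (TSVs are written with fixed formatting).
* Zero catalog columns produce zero exposure columns everywhere; relative
  exposures leave all-zero columns at zero rather than dividing by zero.
* NMF multiplicative updates are floored at $10^{-12}$ to avoid division
  by zero; convergence is declared on a relative objective change below
  `tol`, checked every 10 iterations.
* Degenerate clustering during consensus (an empty cluster, possible when
  the requested rank exceeds the real structure) is retried from other
  bootstrap solutions, then reported with `NA` stability rather than
  being silently patched — an unstable rank is a result.
* Consensus calls key on (chrom, pos, ref, alt) only; chromosome names
  are matched after stripping any "chr" prefix across VCF, BED and FASTA.
  VCF positions are 1-based; BED intervals are converted to 1-based
  inclusive at the boundary. Region restriction is by mutation position
  only, with no padding around loci.
* Variants with N in their context have no valid channel; they are
  excluded and counted per sample in the catalog's exclusion log.
  Non-PASS VCF records are excluded by default (`pass_only = FALSE` to
  keep them) — public call sets do not always document their filtering,
  so the choice is explicit and overridable.

# Known limitations

* Extraction assumes the catalog is a mixture of a *small* number of
  processes; ranks near the sample count are unidentifiable and will be
  reported as unstable rather than prevented.
* The necessity test evaluates one candidate at a time, as the underlying
  procedure does; no multiple-testing correction is applied across
  candidates.
* Forward selection is greedy and can, like all greedy dictionary
  selection, lock in a wrong early choice when references are highly
  collinear; the diagnostics (necessity test, reconstruction errors) are
  the guard rails.
* No rearrangement/indel features, HRD classification scores, extended
  (1536-channel) or transcriptional-strand contexts.
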