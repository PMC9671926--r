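---
title: "Methods: triaging the mechanism of action of a nuclear lncRNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triaging the mechanism of action of a nuclear lncRNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncmoa)
```

`lncmoa` chains six lines of evidence into one reproducible triage of how a
nuclear long noncoding RNA (lncRNA) regulates its target genes: quantitative
expression readouts, consensus protein-interaction prediction, RNA:DNA
triplex search, promoter motif statistics, and transcription-factor (TF)
prioritization. This vignette is the package's methodological account: the
models and their assumptions, every tunable parameter with its default and
rationale, what the synthetic-data generators do and do not emulate, the
numerical choices, and the known limitations.

## Expression analytics

**Model.** RT-qPCR expression is summarized as mean normalized expression
(MNE), $E_\mathrm{ref}^{\overline{Ct}_\mathrm{ref}} /
E_\mathrm{tgt}^{\overline{Ct}_\mathrm{tgt}}$, the efficiency-corrected ratio
of reference to target template. Replicate Ct values enter only through
their mean, so MNE is invariant to replicate order; if both genes share one
efficiency, adding a constant to every Ct cancels exactly, otherwise it
multiplies MNE by $(E_\mathrm{ref}/E_\mathrm{tgt})^c$ — both identities are
asserted in the test suite.

Amplification efficiencies default to 2.0 (perfect doubling) per primer
pair and are accepted per target via arguments; values outside $[1.5, 2.2]$
are rejected as biologically implausible. Knockdown is reported as the
percent change of MNE in the silenced versus control condition within the
stimulated arm, computed per donor (so multiplicative donor effects cancel)
and averaged. Significance uses a two-way ANOVA (stimulation ×
silencing) followed by t contrasts on the pooled residual mean square,
Bonferroni-multiplied by the contrast family size — one contrast per
stimulation level by default, the family a GraphPad-style post test uses on
such designs. Cells with fewer than two replicates are rejected rather than
imputed.

Fractionation percentages divide each compartment's quantity by the sum of
the three compartments (cytoplasm, nucleoplasm, chromatin); the assay rarely
measures an independent total-lysate channel, but when it does, that channel
can be supplied as the denominator. The nuclear share is reported as
nucleoplasm + chromatin. RIP yields use the standard dilution-adjusted
percent of input, $100 \cdot 2^{(Ct_\mathrm{in} - \log_2(1/f)) -
Ct_\mathrm{IP}}$; the input fraction $f$ defaults to 10% as a common bench
choice, not a measured constant — it must be set to the protocol's value.
An IgG percent of input of zero makes fold-over-IgG undefined and is an
error, not an infinity.

## Consensus lncRNA-binding proteins

Two independent predictors reduce each other's false positives. Proteins
present in both score tables are candidates; each gets the mean of the
catRAPID-style interaction score and discriminative power, plus its
lncPRO-style score, and is selected when it exceeds the mean of **both**
scores over the candidate set. Two readings of that rule were open:

* *Which set defines the means?* The intersection (candidates only), since
  only common proteins are comparable across predictors; a `mode = "union"`
  flag computes the means over each full table instead.
* *Strict or weak inequality?* Strict, reading "higher than the average"
  literally; ties are excluded. `strict = FALSE` restores weak inequality.

The realized thresholds are returned next to the selection so they can be
reported like the reference values a published scatter plot would carry;
they are never hard-coded. Functional classification summarizes selected
proteins over the informative classes (transcriptional /
post-transcriptional; `other` and unannotated proteins are excluded from
denominators, which are always reported). The mapping from protein-family
annotations to classes is an input table — no ontology service is consulted.

Protein-binding elements (PBEs) on a per-position interaction profile are
maximal runs of positions scoring at least `threshold` (default 0.5 on a
0–1 profile), with runs separated by fewer than `merge_gap` nt (default 10)
merged and merged runs shorter than `min_length` nt (default 50) discarded —
50 nt is the scale of the stem-loop elements such profiles resolve. Labels
PBE-1, PBE-2, ... follow descending mean score over the element span, gap
positions included.

## RNA:DNA triplex search

A transcriptional regulator that contacts promoters directly must form
triplexes: a single-stranded RNA stretch (the triplex-forming
oligonucleotide, TFO) lying in the duplex major groove and reading the
purine strand through Hoogsteen or reverse-Hoogsteen bonds. The engine uses
the canonical triplet code — parallel (pyrimidine motif) `U·A:T` and
`C·G:C`; antiparallel (purine motif) `A·A:T`, `G·G:C`, `U·A:T` — as an
explicit, inspectable rule set; full triplex-prediction engines add
proprietary extended codes and alignment heuristics that we deliberately do
not attempt to clone, so absolute interaction counts are not comparable
with theirs.

For every promoter, both duplex strands provide a potential purine strand,
and the RNA is aligned in both orientations (parallel: RNA 5′→3′ along the
purine strand; antiparallel: reversed). Along each alignment diagonal the
engine reports **containment-maximal** windows: both endpoints must be
compliant triplets, length ≥ `min_len`, and mismatches ≤
`max_mismatch_rate × length` as a real-valued constraint (no flooring; a
19-mismatch-free window cannot buy a 20th position at rate 0.1). A window
is emitted only if no longer window on the same diagonal also qualifies.
Maximal windows failing the purity filter — purine or pyrimidine fraction
of the target site below `min_purity` — are dropped without re-emitting
their sub-windows; purity is a property of the locus, and a window that
fails it is not rescued by trimming. `N` never matches and counts against
purity.

Defaults: `min_len = 20` nt (stable triplexes need ≥ 20 contiguous
triplets; anything under 10 is rejected outright), `max_mismatch_rate =
0.1`, `min_purity = 0.8`, mismatch penalty 1 in the score
`matches − penalty · mismatches`. Internally the search runs per diagonal
with prefix sums, so a 600 nt RNA against a 5 kb promoter costs seconds; on
sequences ≤ 50 nt it is verified against an exhaustive all-window-pairs
oracle, window for window. TFO windows are merged when they overlap on the
RNA and ranked by (number of supporting target sites, total score), with
genomic coordinate as the final deterministic tie-break; the top region is
TFO1.

## Motif statistics

**Scanning.** Window scores are summed log-odds $\log_2(p_{\mathrm{motif}}
/ p_{\mathrm{bg}})$ in bits. Scores live on an integer grid of `delta` =
1e-3 bit: column scores are rounded to the grid, and the null distribution
of the window score over background-distributed words is the exact
column-wise convolution on the same grid. Because score and null share the
grid, p-values are exactly reproducible by brute-force enumeration over all
$4^w$ words — the test suite does exactly that for widths ≤ 6 — and the
grid error on a reported score is below $w \cdot 5\times10^{-4}$ bits.
Probabilities get an additive pseudocount (`pseudocount = 0.01`, background-
proportional) so zero columns stay finite. `N` scores as the background
expectation of its column score, keeping scan length invariant instead of
truncating windows. Both strands are scanned; a motif wider than the
promoter yields an empty result with a warning.

**Presence-based enrichment.** A promoter "contains" a motif when any
window reaches `scan_alpha` (default 1e-4, the conventional per-window hit
threshold). Presence counts in target versus background promoters are
compared with a one-sided Fisher's exact test, and the reported ratio is
Haldane-corrected, $((t+\tfrac12)/(T+1)) / ((b+\tfrac12)/(B+1))$, so empty
cells stay finite. Note that the expected number of chance hits per
promoter is `2 · L · scan_alpha`: at 1e-4 a 5 kb promoter expects about one
chance hit, and presence saturates in both sets. For long promoters use a
stricter threshold (e.g. `scan_alpha = 1e-5`, or ≈ 0.05/2L for a
per-promoter family-wise rate); the package treats this as an explicit
configuration choice rather than silently rescaling.

**TFBS enrichment.** For a PWM library, the best hit score per promoter is
collected in each set and compared with a one-sided Welch t test (target >
background) — a location test on the promoters actually under study, which
is closer to the question asked than a z test against an organism-wide
background table. Verdicts use the raw `p < 0.05` screening rule that such
candidate triages conventionally apply; a Benjamini–Hochberg column is
reported alongside for readers who want FDR control, but does not change
the verdicts.

**Motif similarity.** Best Pearson correlation of aligned probability
columns over all ungapped offsets with ≥ 4 overlapping columns, both
orientations. The null permutes the columns of the second motif
(`n_perm = 1000`, seeded), and the p-value uses the add-one estimator
$(1 + \#\{r^\ast \ge r\})/(n_{\mathrm{perm}}+1)$. This is a stand-in for
full motif-comparison machinery: adequate for flagging near-duplicates,
not for calibrated cross-database E-values.

## TF prioritization

Evidence for a TF acting at a promoter is scored on the published integer
scale: 0 (no information), 2 (literature-predicted binding site), 6
(literature ChIP), 8 (ENCODE ChIP), 10 (literature **and** ENCODE ChIP).
Flag combinations the scale does not list resolve to the strongest
applicable category (a predicted site never upgrades ChIP evidence); the
full eight-case truth table is pinned in the tests. Duplicate records must
agree or the build fails — conflicting evidence is a curation error to
surface, not to average away.

TF score vectors are clustered hierarchically (Euclidean distance, complete
linkage — chosen for determinism and for producing compact,
diameter-bounded clusters; Ward is available) and cut at `k = 4`, matching
the four-way split such evidence heatmaps typically show. Rows are used
raw: the scores are already on one calibrated scale, and standardizing
would erase exactly the high-versus-low evidence contrast the clustering is
meant to find. `hclust`/`cutree` on a fixed input order provide the
deterministic tie-break.

The "majority" cluster is the one with the largest **coverage** — the
fraction of genes whose within-cluster mean score is positive — with ties
broken by higher mean score; a winner at or below `coverage_threshold`
(default 0.5) triggers a warning rather than an error. Coverage is computed
over the genes present in the evidence table: genes with no evidence for
any TF cannot distinguish clusters and simply do not appear in the matrix.
Final candidates are the intersection of the winning cluster's TFs with the
TFs mapped to significantly enriched binding sites, after case- and
whitespace-normalization of names.

## The synthetic-data generators

Every pipeline input can be generated with planted ground truth
(`simulate_run()` writes a complete run directory plus `manifest.json`;
`verify_truth_manifest()` independently re-reads the files and checks every
planted item). Each generator seeds the global RNG on entry, so identical
calls are byte-identical. Default scales mirror the study design the
package targets: 15 target versus 41 background promoters of 5 kb, a
158-TF evidence table with a 34-TF high-evidence block, 1,000 scored
proteins with 50 planted binders (a desk-scale stand-in for a
2,596-protein genome-wide table), five-donor qPCR designs, ~88% nuclear
localization with a third chromatin-bound, and 6–8× RIP enrichments.

Choices worth knowing about:

* **Promoters** are i.i.d. sequences at 45% GC — the package's
  approximation of upstream regulatory regions. Real promoters have CpG
  islands, repeats and composition gradients; passing tests on this
  background demonstrates correctness of the statistics, not robustness to
  genomic sequence structure. Planted motif instances are sampled from the
  motif's own columns (not consensus), on the `+` strand, non-overlapping.
* **Planted motif sharpness** defaults to a 0.85 dominant-letter
  probability for generic motifs and 0.95 for the binding-site and TF
  libraries in `simulate_run()` — a sharp, well-defined site whose sampled
  instances remain detectable at stringent per-window thresholds on 5 kb
  promoters (see the scan-alpha note above).
* **Evidence background noise is gene-biased**: off-block flags fall on a
  small set of heavily-studied genes (default 5) rather than i.i.d. over
  the matrix. Literature and ENCODE coverage is strongly study-biased in
  reality, and the bias matters for the method: under i.i.d. noise any
  large sparse cluster would touch every gene and trivially win the
  coverage criterion. The block itself covers a fixed 80% majority of the
  genes with ENCODE evidence, plus literature ChIP on half of those cells.
* **qPCR model**: Ct = base − log₂(expression) + Gaussian replicate noise,
  with a per-donor multiplicative expression offset that cancels in
  per-donor percent changes; knockdown multiplies LPS-induced expression by
  (1 − fraction), so at zero noise the recovered percent change equals the
  planted fraction exactly — the closed form the acceptance tests pin.
* **The triplex fixture** plants a pure polypurine tract with pyrimidine
  flanks and the complementary parallel-motif window in the RNA, so at
  `max_mismatch_rate = 0` the maximal hit coordinates equal the planted
  coordinates exactly.
* **What is not emulated**: realistic catRAPID/lncPRO score distributions
  (only their table shapes and a controllable two-channel signal),
  secondary-structure-driven interaction profiles, donor-level covariance
  beyond one multiplicative offset, and genomic sequence structure as
  above.

## Problem sizes and determinism in the shipped tests

The suite exercises the finder-versus-oracle equalities on 200 random
sequence pairs of ≤ 50 nt, the consensus rule against a brute-force filter
on 1,000 random instances of up to 1,000 proteins, exact scan p-values by
full word enumeration for widths ≤ 6, enrichment power on 100 seeded
15-versus-41 promoter sets of 500 nt with presence rates 0.9 versus 0.1,
block recovery over 20 seeds at 5% evidence noise, and one full-scale
(5 kb) end-to-end run executed twice to assert byte-identical summaries.
These sizes keep a complete run of the suite within a few minutes while
leaving every statistical check well-powered; all randomness is seeded in
the tests themselves.

## Known limitations

* The triplex rule set is the canonical code only; no thermodynamic
  stability model, no extended/wobble triplets, no genome-scale indexing.
* Exact scan p-values assume independent background-distributed positions;
  promoter autocorrelation (CpG structure) makes real chance-hit rates
  deviate from the nominal alpha.
* The SEA- and PSCAN-like stages are declared stand-ins: Fisher on
  presence and Welch on best scores, not the original tools' statistics.
* Percent-of-input assumes efficiency 2 on the IP/input pair; primer-pair
  specific efficiencies are supported in MNE but not in the RIP closed
  form.
* The ANOVA post tests assume homoscedastic cells (pooled MSE); no
  mixed-effects donor modeling.
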