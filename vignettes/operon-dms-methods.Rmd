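---
title: "Methods: scoring single-codon saturation libraries of operonic genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring single-codon saturation libraries of operonic genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(operonDMS)
```

## The measurement this package models

A single-codon site-saturation (NNK) library of an operonic gene — the
motivating case is a toxin–antitoxin antitoxin whose activity is essential
for survival of cells carrying the operon — is transformed into a selective
host, grown on plates, and deep-sequenced before and after selection.
Because N = A/C/G/T and K = G/T, each mutagenized codon is replaced by 32
codons encoding all 20 amino acids and one stop (TAG). Enrichment of each
variant's reads across selection, normalized to wild type, is the activity
readout. Downstream, per-variant DNA-sequence features — codon usage,
tRNA abundance, GC content, ribosome stalling, codon adaptation, and
anti-Shine-Dalgarno (aSD) hybridization — are tested for association with
the activity classes.

`operonDMS` implements every stage as composable functions plus a seeded
synthetic-data generator, so the whole analysis can be exercised
end-to-end against known ground truth without any external sequencing
data. The numbered scripts under `analysis/` run one study through all
stages and leave their tables under `results/`.

## Enrichment model

For mutant $i$ with read counts $n_i$ and sample totals $N$ (totals cover
all retained single-mutant plus WT reads),

$$\text{survival}_i =
  \frac{n_i^{\text{sel}} / N^{\text{sel}}}
       {n_i^{\text{unsel}} / N^{\text{unsel}}},
\qquad
\mathrm{ES}_i = \frac{\text{survival}_i}{\text{survival}_{WT}}
  = \frac{n_i^{\text{sel}} / n_{WT}^{\text{sel}}}
         {n_i^{\text{unsel}} / n_{WT}^{\text{unsel}}}.$$

The totals cancel in ES, which is 1 for WT by construction. A replicate
contributes only when the mutant has at least 20 unselected reads; the
reported score is the arithmetic mean over passing replicates
(`n_replicates_used` is recorded). Zero selected reads with a passing
unselected count give ES = 0 — a measurement of complete depletion, not a
missing value — and no pseudocounts are used anywhere. Per-generation
fitness is $w = \mathrm{ES}^{1/g}$ with $w(0) := 0$; the generation count
$g = \lfloor (t_{\text{total}} - t_{\text{lag}}) / t_{\text{double}}
\rfloor$ is 37 for 14 h of plate growth with a 1.4 h lag and a 20.2 min
doubling time (floor and round agree here; floor is kept as the
conservative convention). Phenotypes bin the mean ES: inactive
($\le 0.1$), marginal ($0.1 < \mathrm{ES} < 0.7$), active
($0.7 \le \mathrm{ES} \le 1.5$), hyperactive ($> 1.5$); the bins partition
$[0, \infty)$ with closed boundaries exactly as written. Per-position
summaries report class fractions only for positions with more than 10
scored mutants, and the codon-level dispersion statistic pools
$|ES_a - ES_b|$ over all unordered pairs of codons encoding the same
mutant amino acid at a position, dividing by the total pair count (the
pooled reading of the formula; a per-amino-acid average of averages is the
other defensible reading).

## Read processing

Raw paired reads carry a condition-specific 6-base multiplex identifier
(MID) tag. Processing is: exact-tag demultiplexing (tag stripped;
unmatched reads land in an `unassigned` bin that is counted, never
silently dropped); quality/length filtering with a Phred cutoff of 20 and
a minimum length of 75; merging of mate pairs; alignment; single-codon
variant calling; tallying. Design choices where the procedure itself
leaves room:

* **"Phred cutoff of 20"** is applied to the mean read quality (a
  per-base mode is available via `per_base = TRUE`); the mean reading
  keeps long reads with isolated low-quality cycles, which the identical-
  overlap merge then polices anyway.
* **Merging** requires the maximal exact suffix/prefix overlap (at least
  10 bases) between the forward read and the reverse complement of the
  reverse read to be base-identical; any mismatch discards the pair.
* **Alignment** is Smith–Waterman with match +5 / mismatch −4
  (EDNAFULL-equivalent) and affine gaps with opening 20 and extension 0.5
  — the "water with gap opening raised to 20" setting. Reads equal in
  length to the reference are compared directly instead: that is the
  optimal gap-free alignment under this scoring (one gap costs 20.5
  versus 9 for a mismatch), and a *local* alignment would clip a
  mutation in the terminal codon and mis-classify the read as partial
  coverage. The alignment path handles everything length-discordant.
* **Calling** rejects, with recorded reasons, reads that do not span the
  full reference (`partial_coverage`), contain gaps (`indel`), differ in
  two or more codons (`multi_codon`), or have an ambiguous base in the
  differing codon (`ambiguous_base`). Exactly one differing codon yields
  a variant call; zero yields WT.

### Sequencing-error read thresholds

With Phred quality $q$, the per-base error is $10^{-q/10}$ and the
probability of one *specific* substitution is taken as a quarter of that
("all four bases equally likely"; at Q35 these are 1/3,162 and 1/12,649 —
a division by the three non-reference bases is available but not the
default). The expected count of a specific single-base artifact in $N$
reads is $\lambda = N / 12{,}649$, and the minimum trustworthy read count
is the smallest $k$ whose Poisson upper tail falls below $\alpha$. Three
tail conventions are exposed because the printed threshold of 13 at
$N = 10^5$ is reproduced by the strictly-greater tail $P(X > k)$ (the
default) and by a normal approximation without continuity correction,
while the inclusive tail $P(X \ge k)$ gives 14. The package does not
guess which the original analysis used; it documents the default and
implements all three.

## Ground-truth generator

`assign_true_effects()` endows each variant with a survival drawn from a
log-linear codon-optimality model:

$$s_i = s_0 \cdot \mathrm{RCU}_i^{\beta} \cdot e^{\text{region}(i)}
        \cdot \varepsilon_i,\qquad
  \varepsilon_i \sim \text{Lognormal}(0, \sigma).$$

This is deliberately minimal: it reproduces the qualitative association
the screen is designed to detect (rarer mutant codons survive less) plus
interval-level offsets (e.g. an RBS-overlapping segment) and per-variant
biological noise. Nonsense variants have no defined RCU, so the model
treats their RCU as 1; with $\beta = 0$ and $\sigma = 0$ every variant is
then exactly neutral, which the tests rely on. NNK codons identical to
the reference are folded into the WT pool mass — their reads are
sequence-identical to WT and nothing downstream could distinguish them;
the expected NNK-borne WT fraction is
`carryover + (1 − carryover) · n_K/(32 · n_pos)` with a single
template-carryover parameter (0.073 reproduces the observed ~10% WT from
~2.7% NNK-borne WT). Pool proportions are equimolar across positions and
codons, the natural default when the real per-position balance is
unknown.

Counts are multinomial: unselected at the configured depth from the pool
proportions, selected from proportions reweighted by survival,
replicates independent. FASTQ emission writes full-length amplicon read
pairs (the screen sequenced a 270 bp amplicon fully covering the gene, so
fragmentation is not modelled), MID tag prepended to both mates, constant
or per-cycle Phred qualities, and uniform substitution errors at a
configured rate (indels and PCR amplification bias are out of scope).
Everything is reproducible from a single seed fanned out to stages by
fixed offsets.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: PCR chimera and amplification bias,
quality degradation along cycles, position-dependent error profiles,
per-position pool imbalance, and any biology beyond the injected
log-linear effect (protein stability, mRNA structure, position-specific
effects). The round-trip and recovery results validate the *pipeline*,
not the biology.

## Simulation scales used by the checks

The test-suite studies are sized to be decisive yet desk-scale, and those
sizes are package choices: the exact FASTQ round trip runs a 72-codon
gene with all 71 positions saturated, three replicates at $10^5$ usable
read pairs per condition, error rate 0 — recovered counts must equal the
simulated table *exactly*. Parameter recovery uses a 16-position library
(501 effective variants) at the same depth, with $\beta = 2$,
$\sigma = 1.2$ so true survivals span $[10^{-3}, 10]$ and per-variant
unselected coverage (~180 reads) clears the 20-read cutoff; the seeded
run achieves a log–log Pearson $r \approx 0.99$ between truth and
estimate, classifies every variant with true survival $\le 0.05$ as
inactive, and keeps the median absolute relative ES error under 10%.
Variants with an estimated ES of exactly 0 are excluded from the log–log
correlation (their log is undefined and the no-pseudocount policy is
deliberate).

## Codon features

Relative codon usage follows the within-family normalization
$\mathrm{RCU} = (u_{\text{mut}}/u^{\max}_{\text{mutAA}}) /
(u_{\text{wt}}/u^{\max}_{\text{wtAA}})$; relative tRNA abundance,
relative stalling and relative GC are plain ratios of per-codon values;
base changes is the Hamming distance of the codons; CAI is the Sharp–Li
geometric mean of family-relative weights excluding single-codon families
(Met, Trp) and stops. Where several tRNA species decode one codon their
abundances are summed. The packaged codon-usage table carries standard
E. coli K-12 per-mille values (any consistent scale works, since RCU and
CAI renormalize within families). Measured tRNA-abundance and
ribosome-pausing tables are *not* shipped: the packaged
`*_synthetic.tsv` files are generated stand-ins, labelled as such in
their headers, and every operation accepts user tables — unit-test
correctness never depends on fixture values. Reproducing the original
construct's printed CAI (0.76, with single-codon changes in 0.7–0.78)
would need that exact construct sequence and its 274-gene reference set,
which are external data and out of scope.

## Anti-SD hybridization

Internal SD-like motifs pause ribosomes, and in this operon the
downstream gene's RBS lies inside the upstream coding sequence, so two
scans are provided: a ten-window scan of the 8-nt windows overlapping a
mutated codon (starts from 7 nt upstream of the codon start to 2 nt into
it — exactly the ten placements of an 8-nt window over a 3-nt codon),
reporting per-window energies and the mean mutant-minus-WT difference;
and the predicted RBS strength $\Delta G_{bind}$ of the best 8-nt window
over the RBS region. Since a two-codon RBS interval spans only 6 nt, the
pipeline pads the interval by 5 nt each side (clipped to the gene) so
every window overlapping the RBS codons is scored.

Energies come from a transparent nearest-neighbour RNA/RNA duplex model
rather than a full secondary-structure ensemble: Watson–Crick stack free
energies (Xia et al. 1998 values shipped as a TSV), a single simplified
negative value for any stack involving a G·U wobble, a +4.09 kcal/mol
initiation penalty, no terminal-AU penalties, and no mismatch or loop
structures — only contiguous complementary runs (best sub-run per
registration, best registration overall) pair, and windows that cannot
reach negative energy score 0. The conclusions this module supports are
*differences and rankings* of complementarity to the fixed aSD
(5'-CCUCCUAU-3'), which this model preserves by construction: the perfect
complement is provably minimal, and any single mismatch can only remove
stacks. Absolute energies are not comparable to ensemble predictions; an
`energy_fn` hook lets users plug in an external thermodynamic engine
(e.g. a ViennaRNA wrapper) where absolute values matter. Energies are
reported to one decimal.

## Association statistics

Scored variants split into inactive (mean ES $\le$ 0.1) and active
(> 0.1) classes; each feature's two class distributions are compared with
a two-sided Mann–Whitney rank-sum test — exact for tie-free samples with
combined $n \le 12$, otherwise the normal approximation with tie and
continuity correction (the two agree within 0.02 for group sizes of five
and up, verified by enumeration). Box summaries use linear-interpolation
quartiles with whiskers at the most extreme points inside
$Q_{1,3} \mp 1.5\,\mathrm{IQR}$. Per-feature p-values are reported
uncorrected, matching how such screens report them; a Bonferroni column
is included for transparency but not used for calls.

One statistical caveat surfaced while validating this module and applies
to any analysis of this shape: codon-level features are **pseudo-
replicated** — every mutagenized position reuses the same 31 mutant-codon
values — while the rank-sum test assumes independent observations. When
the activity classes are largely determined by codon identity, a feature
table that is merely *random* with respect to the effect still shows
inflated false-flag rates, because its per-codon sampling noise is copied
across positions. The calibration tests therefore draw their null
features independently per variant (the test's actual null), keep
codon-intrinsic null features (relative GC, base changes) decoupled from
the injected effect by injecting through a random usage table, and take
CAI weights from a separate reference table. Interpreting per-feature
p-values from real libraries deserves the same caution.

Type-I error of the test as wrapped here is calibrated: over 1,000
seeded null simulations at $n = 50$ per group, the rejection rate at
$\alpha = 0.05$ stays within $0.05 \pm 0.02$.

## Pipeline and reproducibility

`run_pipeline()` executes simulate → process → score → features →
sd_scan → associate with stage toggles, enforcing dependencies
(processing needs simulated FASTQ; association needs both scores and
features), writing every intermediate as TSV with a `#` metadata
preamble, and emitting a manifest with version, parameters, seed,
per-stage record counts and output checksums. A single global seed fans
out to per-stage seeds by fixed offsets, so stages are individually
reproducible and statistically independent; identical config + seed gives
byte-identical outputs, FASTQ included. The `analysis/` scripts are the
same pipeline written out as a narrative, one stage per script.

## Known limitations

* The duplex model is a deliberate simplification (see above); absolute
  energies are not ensemble free energies.
* Shipped tRNA and stalling tables are synthetic stand-ins.
* The effect generator is log-linear with lognormal noise; it cannot
  represent epistasis-like position-by-codon interactions beyond interval
  offsets.
* The read processor targets single-gene amplicons with full-coverage
  reads; it is not a general-purpose aligner, does no adapter trimming or
  quality recalibration, and treats indel-containing reads as rejections
  rather than calling them.
* Mann–Whitney p-values on codon-shared features inherit the
  pseudo-replication caveat described above.
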