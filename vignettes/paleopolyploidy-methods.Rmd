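---
title: "Methods: paleopolyploidy inference, TRR calling and synteny-based loss tracing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paleopolyploidy inference, TRR calling and synteny-based loss tracing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`paleoretain` reconstructs the polyploidy history of a set of annotated
genomes and its downstream consequences: which whole-genome duplications
(WGD) or triplications (WGT) each lineage experienced and in what order
relative to speciations; which genomic regions retained the full
post-polyploidy gene complement (triplication-retained regions, TRRs) and
how their composition differs from the genome background; whether a focal
gene family was lost through a local rearrangement; and how gene families
expanded (tandem versus polyploidy-derived duplicates). Because none of
these inferences can be validated directly on real genomes — the true
event history is unobservable — the package pairs every inference stage
with a genome-evolution simulator whose event log is the ground truth.

This vignette documents the models, the tunable parameters with their
defaults and rationale, the numerical choices, and what the simulator does
and does not emulate.

## Synonymous divergence (Ks) estimation

Duplicate and ortholog ages are measured as synonymous substitutions per
synonymous site (Ks), estimated with the Nei–Gojobori counting method:
synonymous and nonsynonymous *sites* are the fraction of the three
possible changes at each codon position that preserve the amino acid
(averaged over the two sequences); *differences* between codons that
differ at two or three positions are averaged over all minimal
substitution pathways, excluding pathways that pass through a stop codon;
single-base changes *to* a stop codon count as nonsynonymous. The
Jukes–Cantor correction
\(d = -\tfrac{3}{4}\ln\bigl(1 - \tfrac{4}{3}p\bigr)\)
is applied separately to the synonymous and nonsynonymous proportions;
\(p_S \ge 3/4\) is flagged saturated rather than extrapolated.

A counting estimator was chosen over codon-model maximum likelihood
deliberately: it is closed-form, dependency-free and exactly reproducible,
and for the quantity that drives every downstream decision here — the
*position* of Ks peaks, not per-pair point estimates — it is sufficient.
Its adequacy is not assumed but demonstrated: on simulator output the mean
estimate over 200 pairs stays within 5% of the planted divergence for
Ks ≤ 1 (the estimator-consistency check in the test suite). The
assumptions inherited from Jukes–Cantor (equal base exchange rates, no
rate variation across sites) are the same ones the simulator's synonymous
process satisfies by construction, which is what makes that consistency
check exact rather than approximate; on real data the estimator shares
the usual biases of counting methods at high divergence.

Unequal-length pairs are aligned first: the translated proteins are
globally aligned (Needleman–Wunsch, BLOSUM62, gap open 10 / extend 0.5),
the alignment is mapped back to codons and gapped codon columns are
removed. Genes whose CDS length is not a multiple of 3 are kept for
synteny but excluded from Ks estimation.

## Anchor chaining into collinear blocks

Homologous anchor pairs (by default, all cross-genome pairs sharing a
family label; self-comparisons use unordered pairs and exclude
self-matches) are chained in *gene-rank* coordinates, not base pairs.
Rank coordinates make chaining invariant to intergenic-length variation —
exactly the property needed when repeat content differs by region — and
base-pair spans are reported afterwards.

A chain's score is \(\sum_i w_i - g \sum (\text{skipped ranks})\) with
gap penalty \(g = 0.2\) per skipped gene on either side, successive
anchors strictly increasing in the reference and strictly increasing
(orientation `same`) or decreasing (`inverted`) in the target, and no
single gap exceeding `max_gap_genes = 25`. Dynamic programming over
anchors is exact (verified against exhaustive enumeration over all
monotone subsets on random instances); chains are peeled off best-first
per chromosome pair and orientation, and blocks with fewer than
`min_block_anchors = 5` anchors are discarded. When a lower-scoring chain
shares anchors with an already-selected block, the shared anchors are
trimmed and the remainder kept if still large enough — this matters for
micro-inversions, whose anchors otherwise vanish into the flanking
collinear block's account. Equal-scoring chains are ordered by start rank
(reference, then target), so output is deterministic. The three chaining
defaults are conventions of this package, exposed in the configuration;
they were fixed before any validation run and match common practice for
gene-level collinearity tools.

## Best-k layouts, syntenic depth and TRR calling

Against a reference genome, each reference gene is assigned the `k`
highest-scoring blocks covering its rank (`k = 3` for a
once-triplicated target; `k = 6` with `min_copies` 4–6 for lineages that
duplicated again), and a region is "present" when the block anchors that
gene. Syntenic depth is the number of present regions — the number of
retained post-polyploidy copies visible through synteny.

TRRs are maximal runs of consecutive reference genes with depth ≥
`min_copies`, tolerating at most `max_gap = 1` consecutive sub-threshold
genes inside a run, discarding runs with fewer than `min_run = 3`
qualifying genes, and always starting and ending on a qualifying gene.
Run length and gap tolerance are deliberately exposed: "consecutive" is
not self-defining, and the defaults (3 genes, 1 interloper) are the
weakest setting that still suppresses single-gene noise.

Composition is measured in sliding windows (width and step configurable;
the window iterator follows the half-open tiling convention with a
flagged partial final window). Within a window, overlapping intervals of
a track are unioned before counting, so no base pair is counted twice.
Windows are assigned to the TRR group by majority base-pair overlap —
border windows go to whichever side holds more than half of them — and
the two groups are compared with a two-tailed two-sample Student's t test
(pooled variance; Welch available behind `var_equal = FALSE`). Groups
with zero pooled variance are reported "degenerate" with no p value
rather than p = 0.

Enrichment of categories among TRR genes uses the exact hypergeometric
distribution, testing both tails — upper for enrichment, lower for
depletion — and reporting the smaller with its direction;
Benjamini–Hochberg adjustment is applied across categories with
significance at adjusted p < 0.01 by default. Functional-domain
enrichment uses two-sided Fisher exact tests per species, BH-adjusted
within species, and a cross-species summary listing domains significant
in at least `min_species = 2` species. Both exact tests are verified
against brute-force enumeration in the test suite.

## Polyploidy-event classification

Per-species paralog Ks distributions and per-pair ortholog distributions
are summarised by Gaussian mixtures on log-Ks. Fitting is restricted to
Ks in `ks_range = (0.01, 3)` — the lower bound suppresses allelic and
assembly noise, the upper bound the saturated tail; both are
configuration, since no principled universal cutoff exists. The component
count (1 to `max_components = 4`) is chosen by BIC, with ties going to
fewer components. Initialisation uses a deterministic quantile-spaced
subset of the sorted data, so refitting identical data reproduces the
identical model without reliance on RNG state.

Peaks are matched across species on the log scale (single-linkage with a
0.3 log-unit tolerance, about 1.35-fold). A matched peak present in
exactly the tips of a clade is assigned to that clade's stem; a peak
private to one species to its terminal branch; any other pattern is
reported `unresolved` rather than guessed. The event's order relative to
the speciation at the top of its branch compares the paralog peak with
the relevant ortholog peak: paralog peak smaller by more than
`min_peak_sep = 0.02` Ks means the event postdates the divergence;
separations inside that band are reported `indistinguishable`. One
subtlety: cross-genome anchor sets contain homeologous (paralog-derived)
matches alongside true orthologs, and their Ks reflects *older*
polyploidy, never younger — so the ortholog divergence peak is taken as
the *youngest* substantial mixture component (weight ≥ 0.15), not the
heaviest one. Event multiplicity (duplication vs triplication) is
annotated from the modal syntenic depth when a depth track is supplied.

A strict-clock conversion \(T = K_s / 2r\) is provided for convenience;
it is a deliberate simplification (one rate, no uncertainty), not a
substitute for proper node dating, and is kept out of every inferential
path.

## Loss tracing and micro-inversion detection

To test whether a family's absence is linked to a local rearrangement,
the reference copy's locus is projected into the target through its
covering block: linear interpolation between the nearest flanking anchors
gives the expected rank, and additionally each flank projects the locus
one-sidedly (flank anchor position plus the rank offset). Around a
rearrangement breakpoint the two flank projections disagree — and that
disagreement is informative: a gene lost at an inversion border sits
adjacent to a breakpoint on at least one side, so border distances are
measured against both projections and the midpoint.

Inversions are detected from anchor order: within the pooled anchors of a
chromosome pair (pooling matters — chaining places a micro-inversion's
anchors in their own small inverted block, so a single block's anchors
cannot show the flip), maximal runs moving against the consensus
orientation with at least 3 anchors are reported with their rank
intervals and gene counts; strand flips are used as corroboration and
reported, but the call itself rests on order, since order is the signal
that survives annotation strand errors. A lost candidate whose projected
locus lies within `border_tolerance = 2` genes of a detected breakpoint
is classified `lost_at_inversion_border`; otherwise `lost`; family
members found inside the block are `retained`, elsewhere `moved`, and a
reference copy outside all blocks is `unresolved`.

## Family dynamics

Clade expansion is tested per family with the two-tailed pooled-variance
Student's t on per-species counts (species missing a family count 0),
with flags at the conventional p < 0.01 / 0.001 / 0.0001 levels;
zero-variance families are "not testable", never p = 0. Duplicate pairs
are classified `tandem` when on one chromosome within
`max_intervening = 10` genes (a common convention for tandem arrays,
exposed as configuration), `wgd_segmental` when the pair is anchored in
an intra-genome synteny block, and `dispersed` otherwise — a partition,
so every pair gets exactly one mechanism. Selection pressure is
summarised as the Ka/Ks distribution and the fraction below 1;
Ks = 0 pairs are reported separately as unratioed. Low-copy-number
marker families require exactly one copy in every required species and
exactly one copy in at least `min_other_single` of the remaining species
(boundary inclusive).

## The simulator: what it emulates, and what it does not

The simulator grows a single-copy ancestor along a rooted binary species
tree with branch lengths, applying events at stated positions on stated
branches: whole-genome multiplication (every chromosome copied, event-
tagged gene ids preserving provenance), biased fractionation (one random
designated survivor per family; each extra copy survives with probability
`retention_prob` times a per-label multiplier, emulating functionally
biased retention), tandem duplication (Poisson per gene, copies inserted
adjacent), inversions and reciprocal translocations, and targeted
single-gene loss, optionally at the border of a micro-inversion whose
size is drawn uniformly from 20–30 genes. Every event is logged with its
payload; replaying the log reproduces each tip's gene count exactly, and
all sampling is drawn from one stream seeded by `seed`, so identical
inputs give byte-identical outputs.

Coding sequences evolve under a code-aware two-rate process: third
positions receive synonymous substitutions at `syn_rate` per synonymous
site (moving uniformly within the codon's synonymous set), first and
second positions receive substitutions at `nonsyn_rate` per site with
changes creating stop codons rejected. The ancestor's codons are drawn
only from fourfold-degenerate families (Ala, Val, Thr, Pro, Gly, Ser),
which makes the synonymous process an *exact* Jukes–Cantor chain at
third positions — the reason the NG86 consistency property can be tested
at a 5% tolerance instead of hand-waved. Multiple hits are simulated
exactly by drawing the per-position event count and sampling the end
state of the corresponding Markov chain, which keeps 500-codon,
multi-thousand-gene genomes affordable.

The repeat landscape is generated at the tips: each intergenic gap gets a
baseline spacer plus an exponential repeat tract (family labels drawn
from a small vocabulary dominated by LTR elements), and inside *retained
runs* — at least 3 consecutive genes whose family kept the full
post-polyploidy complement in the focal species, with one interloper
tolerated, the same convention the TRR caller defaults to — the mean
tract length is multiplied by `repeat_depletion = 0.5`. This couples
retained runs to shorter, repeat-poor intergenic space, which is the
association the TRR composition test is designed to detect.

What the simulator does **not** emulate: insertions and deletions within
coding sequence (alignment is exercised separately on constructed
indels), substitution-rate variation across sites or lineages, gene
conversion between homeologs, realistic repeat sequence (repeats are
intervals with labels, not sequence), intergenic sequence at all,
expression, and positive selection. Consequently, passing tests
demonstrate that the *inference machinery* is correct under its own model
assumptions — chaining is optimal, counting is exact, peaks are placed
where the divergence process puts them, TRR calls match planted retention
— not that real genomes satisfy those assumptions. On real data,
alignment error, rate variation and saturation will widen Ks peaks and
blur event ordering in ways these tests do not measure.

### The demonstration scenario

The canonical three-taxon scenario (`trio_scenario()`) fixes the study
conditions: two ingroups and an outgroup on
`((A:0.4,B:0.4):0.45,O:0.85):0.75`, with the synonymous clock at 0.5
substitutions per site per unit time so branch lengths read directly in
pairwise-Ks units. An old triplication at the start of the root stem
gives every species a paralog peak at Ks 1.6 (the ancient-eudicot-
triplication regime); a younger triplication on the ingroup stem at
Ks 0.8 sits just inside the ingroup–outgroup ortholog divergence at
Ks 0.85, so the event is correctly ordered *after* that speciation but
close to it; each triplication is followed by fractionation at retention
probability 0.5 with a 1.6× bias toward `fattyacid`-labelled genes; and
the ingroup stem carries one targeted gene loss at a micro-inversion
border. Validation problem sizes — 2 000 ancestral genes and 500-codon
CDS for event recovery, 300 codons and 200 pairs for estimator
consistency, 100 replicates for loss classification, 30-kb windows for
composition — are the package's chosen desk-scale settings: large enough
that binomial noise sits well inside the stated tolerances, small enough
to run in minutes.

## Known limitations

* NG86 + Jukes–Cantor underestimates divergence under transition/
  transversion bias or codon-usage bias; peak *positions* shift
  accordingly on real data. Peak separation, not absolute position,
  carries the event-ordering signal.
* Family-based anchors cannot distinguish which post-polyploidy copy a
  target gene descends from; best-k layouts resolve this spatially, but
  in lineages with nested polyploidies the per-gene depth track measures
  the most recent event only when the reference itself predates it.
* Mixture-model component counts are sensitive to skewness of the log-Ks
  distribution; a single biological peak can be fitted by two adjacent
  components. The cross-species peak matching tolerance (0.3 log units)
  absorbs this, but reported component tables should be read with that
  in mind.
* The loss classifier assumes the rearrangement is visible as anchor
  disorder within one chromosome pair; losses mediated by rearrangements
  spanning assembly gaps or chromosome fusions are out of reach.
* `ks_to_time()` is a strict clock and should not be used where proper
  dating matters.
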