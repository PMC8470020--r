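---
title: "Profiling the metabolic potential of mud-volcano MAGs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling the metabolic potential of mud-volcano MAGs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magpot)
```

`magpot` covers the desk-scale half of a sediment-metagenome survey: it
takes per-MAG protein sets and annotation tables (plus ASV tables, qPCR
runs, tracer incubations and a genome-bin ledger) and produces the
community's metabolic portrait — who carries multiheme cytochromes, who can
fix CO₂, who reduces nitrate or oxidizes sulfur, how diverse the amplicon
community is, and how abundant the target group is in absolute terms. This
vignette explains each model, the tunable parameters and their defaults,
the choices made where the design was genuinely open, and what the
synthetic-data tests do and do not demonstrate.

## Multiheme cytochrome detection

A c-type heme binds covalently at the CxxCH motif: cysteines at positions
1 and 4, histidine at position 5, any residues between. `find_heme_motifs()`
scans **every** start position, so overlapping motifs are all counted; the
anchor letters match only literal `C`/`H`, while the two wildcard positions
accept anything, including ambiguity codes. The motif is exactly C-x-x-C-H;
longer variants (CxxxCH, CX15CH) occur in nature but are rare and would
require family-specific evidence, so they are not matched — users needing
them can pre-process sequences or post-filter candidate proteins
themselves.

A protein is called an MHC at `min_motifs = 2` (one heme makes a monoheme
cytochrome; surveyed genomes encode MHCs with as few as two motifs). The
per-MAG roll-up reports the count, the count with *strictly* more than ten
motifs, the maximum in a single protein, and the number with a predicted
C-terminal membrane anchor.

Membrane anchoring uses a Kyte–Doolittle sliding window because no single
published predictor is canonical for this screen and a transparent,
parameterized rule is easier to audit: window 19 residues (odd, the classic
helix-spanning width), mean hydropathy threshold 1.6 (the conventional
cutoff for putative transmembrane segments on the KD scale), and the
window must start within the last 40 residues to count as C-terminal. All
three are arguments; ambiguity codes score 0 (neutral). Ties between
windows are resolved toward the highest-scoring window; because rolling
means are computed by cumulative sums, exact ties can differ in the last
floating-point digit — the reported span is always *a* maximal-scoring
window.

Calling criteria for MHCs are not standardized across studies; counts on
real genomes therefore depend on the annotation pipeline and these
parameters, which is why the package tests recovery on planted synthetic
truth rather than asserting any published per-genome count.

## CO₂-fixation completeness and autotrophy calls

Each of the seven known carbon-fixation pathways — Calvin–Benson–Bassham
(CBB), reductive acetyl-CoA (Wood–Ljungdahl, WL), reductive TCA (rTCA),
3-hydroxypropionate bicycle (3-HP), 3-hydroxypropionate/4-hydroxybutyrate
(3-HP/4-HB), dicarboxylate/4-hydroxybutyrate (DC/4-HB) and the reversed
oxidative TCA (roTCA) — is described by an essential-gene set in the KEGG
orthology namespace plus diagnostic key genes (RuBisCO for CBB, the CO
dehydrogenase/acetyl-CoA synthase core for WL, ATP-citrate lyase for rTCA,
citrate synthase for roTCA, and so on). The shipped
`carbon_fixation_pathways.yaml` is a curated default — editable, and
replaceable wholesale via `load_pathway_definitions(path)` or per pathway
via `override` — because the precise gene list behind any published heat
map is a curation choice, not a universal constant.

Completeness is binary set arithmetic:
`100 · |essential ∩ annotated| / |essential|`. Copy number never weights a
cell, and multi-subunit complexes count one identifier per subunit. Cells
are monotone under annotation supersets, and a cell is 100 exactly when
the essential set is covered.

"Full genomic potential" — an autotrophy call — defaults to 100%
completeness plus all key genes (`threshold` and `key_gene_guard` are
arguments, since published cutoffs are rarely stated). The roTCA cycle
carries an extra guard: because its essential set is essentially the TCA
cycle plus citrate synthase, and citrate synthase is ubiquitous in
heterotrophs, a roTCA call requires the complete essential set regardless
of the threshold. This encodes the common situation where several genomes
carry the key enzyme but an incomplete cycle, and no roTCA autotrophy
should be claimed.

Note one consequence of real pathway biology: the TCA-adjacent pathways
share genes, so planting genes for one pathway raises sibling cells. The
tests therefore assert exact fraction recovery on the planted pathway and
verify the remaining cells by independent set arithmetic.

## Marker genes and the metabolism rule order

`marker_catalog.yaml` maps marker symbols to annotation-identifier
aliases; a marker is present when any alias is annotated (so `dsrAB` fires
on `dsrA` or `dsrB`, the `sox` cluster on any subunit). The
reverse-methanogenesis check asks three questions of a MAG: are all seven
central methanogenesis steps (fmd, ftr, mch, mtd, mer, mtr, mcr) encoded;
are the canonical hydrogenases of methanogens (Ech, Vho, Mvh, Frh) absent;
are the methylotrophy methyltransferases absent. Only then is the genome a
"reverse methanogenesis" candidate — a methanotroph running the
methanogenic pathway backwards — rather than a methanogen. The check also
reports nitrate- and sulfate-reduction gene groups and the Fpo/Hdr/Rnf
electron-transfer complexes for electron-acceptor reasoning.

Putative-metabolism labels come from a fixed rule order over the presence
row, the autotrophy call and the reverse-methanogenesis verdict. No
published study states a formal decision procedure for such summary
labels; the order implemented here is a *reconstruction*, chosen so that
the packaged 33-bin marker-set table reproduces its recorded label column
exactly, and it is configuration to be read, audited and disagreed with:

1. reverse-methanogenesis candidate → *anaerobic methane oxidation*;
2. pMMO → *aerobic methane oxidation*;
3. autotrophy call → *autotrophic*;
4. dsrAB → *sulfite/sulfate reduction*;
5. narG ∧ nosZ → *denitrification* (replacing, not joining, *nitrate
   reduction*); else napA ∨ narG → *nitrate reduction*; nosZ alone fires
   nothing (a lone terminal reductase is weak evidence of a denitrifying
   lifestyle);
6. sox ∨ sqr ∨ soeA → *sulfur compound oxidation*;
7. coxA → *facultatively anaerobic* when a periplasmic [FeFe] hydrogenase
   (a fermentation marker) co-occurs, else *aerobic*. Only the aa₃-type
   oxidase asserts an aerobic lifestyle; the cbb₃-type ccoN alone is a
   microaerobic adaptation and fires nothing. The bare lifestyle label is
   suppressed for autotrophs and aerobic methanotrophs, whose trophic
   label already carries the information;
8. Fe-hyd with no respiratory acceptor genes → *fermentation*;
9. hybC ∨ hyaB → *H₂ utilization*, unless the bin is fermentative (the
   uptake hydrogenase is then part of that metabolism) or an autotroph
   with no anaerobic respiratory acceptor (where H₂ feeds CO₂ fixation
   rather than constituting a separate trophic strategy);
10. GH1 → *carbohydrate utilization*; 11. bzd → *aromatic compound
    utilization*; 12. complete WL ∧ cooS ∧ cooF → *acetogenic*;
13. otherwise *Unidentified*, never combined with another label.

Two properties follow and are tested: labels are invariant to annotation
row order, and the donor-utilization labels only accumulate as markers are
added. The lifestyle summaries (*aerobic*, *facultatively anaerobic*,
*fermentation*) are deliberately exclusive — adding an oxidase to a
fermenter reclassifies it — so global monotonicity is not a property of
this labelling and is not claimed.

## Diversity statistics

Chao1 uses the bias-corrected form `S_obs + f1(f1−1)/(2(f2+1))`, which is
defined even without doubletons and equals the vegan implementation (used
as a cross-check in the tests, never as the implementation). Shannon
defaults to natural logarithms — an observed H of ~5 on ~750 ASVs is only
consistent with nats, the maximum being ln(744) ≈ 6.6 — with base 2 behind
a flag. Coverage is `100 · S_obs / Chao1`, reported both at full precision
and rounded for display; alternative coverage estimators (Good's) are out
of scope.

The optional corrected-singleton Chao1 addresses singleton inflation by
sequencing errors: the observed `f1` is replaced before the classic
formula by a moment estimate from higher-order frequency counts. Under a
Poisson model for rare species, `f_k ∝ λ^k/k!`, the doubleton/tripleton
ratio estimates λ as `3f3/f2`, giving `f1_hat = 2f2²/(3f3)`. This is the
implemented convention, documented as such; when `f3 = 0` the variant is
undefined and the classic estimator is used with a warning. The default
path never depends on it.

Taxonomy aggregation parses semicolon-delimited lineage strings, groups
unassigned ASVs as `unclassified`, reports percentages summing to 100, and
applies the display convention of community bar plots: only groups
*strictly above* 1% are shown, the remainder pooled into `other`.

## qPCR and tracer quantification

A standard curve is the least-squares line of Cq on log10(copies);
efficiency is `E = 10^(−1/slope) − 1` (slope −3.3219 ⇔ 100%). At least
three standards over at least two decades are required; R² is computed
directly from residuals. Efficiencies below 70% are flagged with a warning
but still reported — environmental DNA with co-extracted inhibitors
genuinely produces such curves, and discarding them would misrepresent the
assay. Copy numbers interpolate as `10^((Cq − intercept)/slope)`, scale by
a volume basis, and aggregate per label as mean ± sample SD (n − 1).

The tracer rate convention is
`rate = (a_product / a_total) · CH₄ pool / days` per replicate — the
fraction of added labelled methane recovered in oxidation products, scaled
to the pool and normalized per day — with the mean killed-control rate
subtracted and negative results clamped to zero with a warning. Whether
`a_total` should include only recovered methane or methane plus products
differs between laboratory protocols; the implemented convention (total
added activity) is stated rather than inferred, and replicate aggregation
is mean ± sample SD to match the usual "± SD, n = 3" reporting.

## The genome-bin ledger

Completeness bands use half-open intervals `[lo, hi)` with an exact-value
band (both ends closed) for 100%: the partition
`[0,85) ∪ [85,90) ∪ [90,100) ∪ [100,100]` covers any ledger, which is a
tested property. Narrative band labels in survey texts ("90–98%") tend to
describe occupied sub-ranges rather than the counting rule; the implemented
band is the interval, documented here. A 16S gene counts as complete at
strictly greater than 1400 bp. Phylum roll-ups use an explicit bin→phylum
mapping (shipped for the packaged ledger, since its taxon column mixes
ranks) or lineage-substring matching; unresolved bins are reported in an
attribute, never silently dropped. Abundance sums display at 1 d.p. —
rounded and full-precision inputs give the same displayed values on the
packaged ledger. The giant-protein genome fraction is
`100 · 3 · length_aa / genome_bp`.

This is an analysis package in the vegan/phyloseq mold: the exported
functions, scripts and vignette are its interface, and no shell entry
point is shipped — R users drive these stages interactively or from small
scripts like `scripts/acceptance.R`.

## What the synthetic generators emulate — and what they do not

The generators produce inputs with the statistical structure the
downstream stages assume, with defaults chosen to mirror a realistic
methane-seep workup:

* **Proteins.** Background sequences use UniProt-like residue frequencies
  and are guaranteed motif-free by rewriting the His anchor of any
  accidental CxxCH (rejection-with-rewrite keeps composition realistic;
  restricting the alphabet would not). Planted MHCs sit on a Cys/His-free
  scaffold so they carry *exactly* the requested motif count, and planted
  membrane anchors are 21 consecutive residues from {L, I, V, F, A}
  placed within the last 40 positions — guaranteed to trip the default
  detector. Length range defaults to 120–400 aa.
* **Annotations.** Pathway gene subsets are seeded shuffle-then-prefix,
  taking exactly `round(fraction · |essential|)` genes — deterministic and
  uniform; marker symbols expand to all catalog aliases.
* **ASV tables.** Relative abundances follow a log-normal (σ = 1.5
  default) or Fisher log-series (x = 0.995) shape — conventional stand-ins
  for microbial community structure, not claims about any particular
  sample — and reads are multinomial, so depth is conserved exactly.
* **qPCR.** Cq values sit on the theoretical line for the requested
  efficiency (default 100%, intercept 38 at one copy, six ten-fold
  standards) plus Gaussian noise; standards and samples are run in
  triplicate.
* **Tracer.** Defaults reproduce a typical sediment incubation: ~12.8
  nmol cm⁻³ of labelled methane (1 µCi at 1.16 GBq mmol⁻¹ in 2.5 cm³),
  5 days, 5% activity noise, triplicates, and a killed control at a
  0.02 nmol cm⁻³ day⁻¹ blank.

What passing tests on these inputs shows: the scanner, scorer, rule engine
and estimators are *correct implementations of their definitions* — exact
recovery of planted truth, agreement with brute-force oracles and
independent implementations. What it does not show: performance on real
data, where annotations are incomplete and wrong, motif calling meets
pseudogenes and fragments, abundance distributions are messier than any
two-parameter model, and qPCR inhibition is not Gaussian. The packaged
ledger and marker-set tables are transcriptions of a real survey's summary
statistics and anchor the roll-up arithmetic to real numbers, but the
upstream measurements behind them (assembly, binning, CheckM, amplicon
denoising, wet chemistry) are inputs here, not reproduced computations.

## Problem sizes and numerical conventions

The test suite runs at desk scale by design: 500–1000 random 200-mers for
the oracle properties, 10–30 seeded synthetic MAGs per recovery property,
50 replicate ASV tables, 100 qPCR noise replicates, 25 tracer replicates —
enough for the exact properties (which hold for *every* case) and stable
for the stochastic coverage checks. Display rounding is fixed (coverage to
integers, H to 2 d.p., abundance sums to 1 d.p., fractions to 2 d.p.) with
full precision always retained in returned objects. All generator
determinism flows through a single seed-scoping helper that restores the
caller's RNG state.

## Known limitations

* Annotation quality bounds everything: the profiler trusts its input
  table and performs no homology search, HMM scan or gene calling.
* The default pathway gene sets and the marker catalog are curations;
  swapping them changes completeness cells and labels, which is why both
  are plain YAML.
* The metabolism rule order is one defensible reconstruction; other
  orders reproduce other tables. The evidence trail on every label exists
  precisely so users can audit disagreements.
* TM prediction by hydropathy window has no notion of topology, signal
  peptides or beta barrels.
* The corrected-singleton Chao1 variant implements a stated Poisson-moment
  convention; other singleton-correction estimators exist and will give
  different values on singleton-rich tables.
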