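---
title: "Methods behind phosmine: marker filtering, gene distances, signatures, kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind phosmine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosmine)
```

phosmine mines prokaryotic genome sets for phosphonate biosynthetic gene
clusters anchored on phosphoenolpyruvate mutase (Ppm) and quantifies the
enzymology of the phosphonyl-tailoring cytidylyltransferases (PntC) those
clusters encode. This vignette records the models, the tunable parameters
and their defaults, the numerical choices, and the places where the design
was genuinely open and a decision had to be made.

## Marker detection and hit quality

Ppm candidates are proteins matching the Pfam profile HMM PF13714
(PEP mutase / isocitrate lyase family). Hits come in as HMMER3
`--domtblout` tables; phosmine consumes the table rather than running the
search, so any HMMER version or wrapper can sit upstream.

Two quality filters are applied, both inclusive:

* **Gathering threshold.** Family membership uses the Pfam-curated GA
  bit-score cutoff. domtblout does not record GA status, so the parser
  assumes searches were run with `--cut_ga` (every emitted row passed);
  when that guarantee is absent, a per-family GA table
  (`ga_table = c(PF13714 = ...)`) recomputes `meets_ga` from the
  per-domain bit score.
* **Model coverage.** A hit must cover at least 60 % of the *model*:
  `(hmm_to − hmm_from + 1) / model_length ≥ 0.6`. The denominator is the
  HMM length, not the query length, because the criterion is alignment to
  the family model; a fragment matching 59 % is dropped, exactly 60 % is
  kept. Split domains are judged per hit by default; with
  `coverage_by = "protein"` the union of model columns covered by all
  fragments of one protein × family is pooled first, which rescues
  genuinely split domains at the cost of occasionally rescuing repeats.

Overlapping domain hits on one protein are resolved greedily: hits are
visited in order of decreasing per-domain bit score (ties: smaller
`ali_from`, then input order, making the output deterministic) and kept
iff their protein-coordinate interval shares no residue with an
already-kept hit. Overlap is defined on 1-based inclusive intervals; a
`max_overlap` tolerance (default 0 residues) is exposed because domain
boundaries from local alignments are fuzzy by a few residues.

## The catalytic motif

PF13714 covers both PEP mutases and isocitrate lyases, so family
membership over-calls Ppm by more than an order of magnitude. The
catalytic motif `E-D-K-x(5)-N-S` separates the two. The scanner reports
every occurrence, overlapping ones included, over the full protein
sequence — the motif is not assumed to sit inside the PF13714 alignment
envelope, since domain envelopes from local alignment can clip catalytic
residues. Ambiguous `X` residues match the five wildcard positions but
never the literal anchors: an ambiguous residue should not *create* a
motif call. The pattern is configurable (`"EDKx{5}NS"` grammar) so the
same machinery scans other anchored motifs.

## Fusion inventory

Exact duplicate sequences (case-insensitive string identity) are
collapsed before counting, with the representative chosen as the first
protein id in sort order — deterministic and reproducible. Anything
looser than exact identity (clustering at 90 % identity, say) answers a
different question and is out of scope.

Each non-redundant Ppm protein is classified from the non-PF13714
accessions among its resolved hits: none → ALONE; PF12804 only →
NTP_TRANSF_3; PF01467 only → CTP_TRANSF_LIKE; both → TRIPLE; anything
else → OTHER. When a named nucleotidyltransferase partner co-occurs with
an unrelated extra domain the named partner wins by default
(`strict_other = TRUE` reverses this); the alternative would silently
shrink the nucleotidyltransferase categories whenever an accessory domain
tags along.

Two percentage denominators coexist on purpose. The share of fused
sequences among all non-redundant PF13714 matches uses the pre-motif
denominator; the category percentages ("% of Ppm proteins") use the
motif-positive denominator. Both are reported, unrounded values alongside
1-decimal rounding (half away from zero, since base R's round-to-even
would print 2.8 for 2.85).

## Gene distances

Genes are indexed 0, 1, 2, … along each replicon by ascending GFF3 start
coordinate, strand ignored. The distance between two genes is the
absolute index difference: adjacent genes are 1 apart, one intervening
gene makes 2, and a nucleotidyltransferase domain fused onto the Ppm
polypeptide is at distance 0. This is the only reading of "distance in
genes" that gives fusion distance 0 and admits every positive integer.
Per genome, only the closest *ppm* × nucleotidyltransferase pair is
tabulated, pairs never cross replicons, and genomes lacking either role
contribute nothing. Replicons are linear by default — draft assemblies
dominate real collections — with circular arc distance behind
`circular = TRUE`. The nucleotidyltransferase role defaults to
PF12804/PF01467 and is configurable (e.g. adding PF00483/PF01129 for a
wider retrieval net).

## Trinucleotide signatures and dereplication

A genome's signature is the 64-vector of relative frequencies of all
overlapping 3-mers counted over every sequence record *and its reverse
complement* (so the signature is strand-invariant); windows containing
non-ACGT characters are skipped rather than randomized, for determinism.
The distance between genomes is the mean absolute difference of the 64
components, scaled ×100 so the species-level cutoff operates at
δ = 0.03. The precise distance and normalization conventions of
oligonucleotide-signature dereplication vary between implementations;
the choices here (plain two-strand frequencies, scaled L1 mean, greedy
leader clustering over genomes sorted by descending total length then id)
are explicit, configurable and deterministic, and they reproduce the
intended contract — mutated replicates of a genome cluster with it, while
independent genomes of the same composition stay apart.

On 20 kb uniform-random genomes, ~1 % per-site substitution leaves
replicate pairs at signature distance well inside δ = 0.03 while
independent genomes sit several-fold beyond it; the dereplication tests
plant their three-species suites at that divergence. Real genomes carry
compositional structure (GC skew, codon bias) that moves absolute
distances, so δ should be recalibrated before applying the default to a
real collection.

## Kinetics

Initial-rate data are fit by bounded Levenberg–Marquardt least squares
(minpack.lm) to

* Michaelis–Menten: `v = kcat·E0·S/(KM + S)`
* substrate inhibition: `v = kcat·E0·S/(KM + S(1 + S/KS))`

with S, KM and KS in one concentration unit (conventionally mM) and E0 in
molar. The substrate-inhibition form above is the standard uncompetitive
single-site law; its internal consistency is enforced by using the same
form in the data generator and the fitter, and it has the testable
property that the velocity maximum sits at `S* = √(KM·KS)`.

Numerical choices: starting values `kcat₀ = max(v)/E0`, `KM₀ = S` at
half-maximal observed velocity, `KS₀ = max(S)`; all parameters bounded
positive; convergence tolerances 1e-15 so noiseless data are recovered to
≈1e-6 relative or better. The substrate-inhibition surface can hold
shallow local minima on sparse designs, so the fitter runs a small
deterministic grid of starting points (kcat ×{1,2}, KM ×{0.2,1,5},
KS ∈ {max(S)/5, max(S), 5·max(S)}) and keeps the best residual sum of
squares. Standard errors are asymptotic, from a central-difference
Jacobian at the optimum; when `KS` runs beyond 100 × max(S) the model is
locally indistinguishable from Michaelis–Menten, the Jacobian becomes
singular in that direction, standard errors degrade to `NA`, and the fit
warns that inhibition is not identifiable — it does not fail, because the
remaining two parameters are still well determined.

Specificity constants `kcat/KM` are reported in M⁻¹ s⁻¹ (mM inputs are
converted), and substrate-preference ratios are rounded half away from
zero to 2 significant figures, the convention under which fold-preference
values are quoted.

## What the synthetic generator emulates — and what it does not

`generate_bundle()` emits, per declared genome: one protein per gene
(FASTA), a GFF3 gene table whose start coordinates define gene order, an
hmmscan-style domtblout with one PF13714 row per planted Ppm (model
coverage configurable, default 0.8; set below 0.6 for negative controls)
plus partner-domain rows on non-overlapping coordinates, and a random
nucleotide sequence per replicon. Background protein sequences are i.i.d.
uniform over the 20 amino acids, which makes an accidental catalytic
motif a ~(1/20)⁵-per-window event; the generator additionally scrubs any
accidental occurrence so motif truth is exact rather than merely
overwhelmingly probable. Planted gene distances are realised exactly; a
planted distance of 0 becomes a fusion partner on the Ppm protein itself,
never a separate gene. Everything is deterministic given the spec's seed.

Deliberately not emulated: realistic codon usage or GC structure in the
nucleotide sequences, HMM bit scores derived from actual profile HMMs
(scores are placeholders consistent with the planted architecture),
indels in `mutate_genome()` (substitutions only, length-preserving), and
taxonomic structure beyond what signature mutation induces. Passing the
round-trip tests therefore demonstrates that the pipeline's bookkeeping —
filtering, classification, indexing, distance and dereplication logic —
is exact; it does not validate HMM search sensitivity or real-genome
signature calibration.

## Problem sizes used in the checks

The bundled verification runs use 20 synthetic genomes of 15–20 genes for
the round-trip suite, ≥100 random instances per brute-force-oracle
comparison (coverage filter, overlap resolution, motif scan, 3-mer
counts), 200 Monte-Carlo replicates at 5 % multiplicative noise for
fitter bias, and 9 genomes (3 planted species × 3) of 20 kb for
dereplication — sizes at which every check runs in seconds while leaving
the combinatorics non-trivial.

## Known limitations

* `meets_ga` is trusted from the upstream search unless a GA table is
  supplied; phosmine never recomputes family membership from raw scores
  on its own.
* Exact-duplicate deduplication only; no identity-threshold clustering.
* The signature distance and δ default are calibrated on synthetic
  uniform-composition genomes; real collections need a sanity check of
  the distance distribution before trusting "one per species".
* Kinetic standard errors are linearized asymptotic values, not
  bootstrap or profile-likelihood intervals.
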