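# phosmine

Genome mining of phosphonate biosynthetic gene clusters, plus the enzyme
kinetics used to characterise the tailoring enzymes those clusters encode.

Phosphonates are natural products built on a direct carbon–phosphorus
bond. Their biosynthesis is almost universally initiated by
phosphoenolpyruvate mutase (**Ppm**), which isomerises PEP to
phosphonopyruvate, so *ppm* genes are the standard marker for finding
phosphonate gene clusters in genome collections. Ppm belongs to the Pfam
family PF13714, but that family also contains isocitrate lyases; a bona
fide PEP mutase is distinguished by the conserved catalytic motif
**EDKXXXXXNS**. A striking feature of Ppm proteins is how often they are
fused to a nucleotidyltransferase domain — the MobA-like NTP transferase
(PF12804) or the cytidylyltransferase-like domain (PF01467) — the
signature of phosphonyl-tailoring cytidylyltransferases (**PntC**) that
activate phosphonates such as 2-aminoethylphosphonate (AEP) as CDP
conjugates. phosmine implements the comparative-genomics workflow built
around these observations, for anyone mining prokaryotic genome sets for
phosphonate biosynthesis:

1. **Domain-hit filtering** — parse HMMER3 `--domtblout` tables; keep a
   hit iff it passed the family's gathering (GA) threshold and covers at
   least 60 % of the profile HMM, `(hmm_to − hmm_from + 1)/L ≥ 0.6`;
   resolve overlapping domains per protein greedily by descending
   per-domain bit score.
2. **Motif calling** — scan protein sequences for `E-D-K-x(5)-N-S`
   (all occurrences, overlapping included; ambiguous `X` residues never
   satisfy an anchor).
3. **Fusion inventory** — deduplicate exact sequences, classify each Ppm
   protein as ALONE / NTP_TRANSF_3 / CTP_TRANSF_LIKE / TRIPLE / OTHER
   from its resolved partner domains, and summarise counts and
   percentages.
4. **Gene-neighbourhood distances** — index genes 0,1,2,… along each
   replicon by ascending GFF3 start coordinate and tabulate, per genome,
   the distance in genes between *ppm* and the nearest
   nucleotidyltransferase gene (0 = fused on the same polypeptide).
5. **Genome dereplication** — 64-component trinucleotide signatures
   (3-mer frequencies counted on both strands), mean-absolute-difference
   distance scaled ×100, greedy leader clustering at δ = 0.03 to keep
   roughly one genome per species.
6. **Enzyme kinetics** — nonlinear least-squares fits of
   `v = kcat·E0·S/(KM + S)` and the substrate-inhibition law
   `v = kcat·E0·S/(KM + S(1 + S/KS))`, specificity constants
   `kcat/KM` (M⁻¹ s⁻¹) and substrate-preference ratios.

A synthetic-genome generator (`genome_spec()` → `generate_bundle()`)
plants Ppm homologs, motifs, fusion architectures, neighbouring
nucleotidyltransferase genes, exact duplicates and genome replicates with
known ground truth, so the entire pipeline is testable end to end without
downloading any database.

## Worked example

```r
library(phosmine)

spec <- genome_spec(
  "demo",
  replicons   = data.frame(replicon_id = "chr", n_genes = 12),
  planted_ppm = data.frame(replicon_id = "chr", gene_index = 4,
                           has_motif = TRUE),
  planted_ntf_distances = data.frame(replicon_id = "chr",
                                     ppm_gene_index = 4, distance = 2),
  seed = 42)
paths  <- write_bundle(generate_bundle(spec), tempfile("demo"))
report <- run_ppm_pipeline(pipeline_config(
  proteins = paths[["proteins"]], gff = paths[["gff"]],
  domtblout = paths[["domtblout"]], genomes = paths[["genome"]]))
report
#> phosmine pipeline report
#> Ppm fusion inventory
#>   PF13714 matches (raw):       1
#>   non-redundant sequences:     1
#>   fused (non-redundant):       0 (0.0%)
#>   motif-positive (Ppm):        1
#>   ...
#> ppm-NTF nearest gene distances: 1 genomes
#>   fused (distance 0):   0.0%
#>   within 5 genes:       100.0%

distance_plot_table(report$distribution)
#> # A tibble: 1 × 4
#>   distance count log10_count cumulative_fraction
#>      <int> <int>       <dbl>               <dbl>
#> 1        2     1           0                   1
```

The planted *ppm* gene is recovered as a stand-alone, motif-positive Ppm
whose nearest nucleotidyltransferase gene sits exactly 2 genes away — the
planted truth.

Kinetics, with the AEP-preferring cytidylyltransferase parameters
(kcat = 3.7 s⁻¹, KM = 0.012 mM):

```r
d   <- generate_kinetic_dataset(kcat = 3.7, KM = 0.012, E0 = 1e-8,
                                S_grid = 0.012 * c(0.1, 0.5, 1, 2, 5, 25))
fit <- fit_michaelis_menten(d, E0 = 1e-8)
glance(fit)
#> # A tibble: 1 × 8
#>   model  kcat    KM    KS   rss     n converged kcat_over_KM
#>   <chr> <dbl> <dbl> <dbl> <dbl> <int> <lgl>            <dbl>
#> 1 MM      3.7 0.012    NA     0     6 TRUE           308333.

# ~440-fold preference for AEP over phosphocholine
specificity_ratio(specificity_constant(3.7, 0.012),
                  specificity_constant(0.7, 1.0))
#> [1] 440
```

Fitted objects support `tidy()`, `glance()` and `autoplot()`; the report,
inventory and distance distribution have `print()`, `tidy()`/`glance()`
and `autoplot()` methods.

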