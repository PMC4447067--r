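# sigchip

Characterization of a bacterial sigma-factor regulon from ChIP-seq data,
with a synthetic experiment generator that makes every analysis stage
verifiable against planted ground truth.

In *E. coli*, the stress sigma factor σ^S (RpoS) redirects RNA polymerase
(Eσ^S) to the general stress regulon as cells enter stationary phase.
ChIP-seq of tagged σ^S compares an immunoprecipitated (IP) library against
a sonicated whole-genome Input library; genomic intervals significantly
enriched in the IP ("peaks") mark Eσ^S binding sites, which are then
attributed to the promoters and genes they cover, and the −10 promoter
elements beneath them are aligned to expose σ^S-specificity determinants
(−13C/−12C, −8C, −6T, and an A/T-rich discriminator between the −10
hexamer and the transcription start).

`sigchip` provides:

* **Peak calling** — a one-sided Poisson window test of IP fragment counts
  against a locally estimated Input background,
  `p = P(X ≥ ip_count), X ~ Poisson(λ)`,
  `λ = max(window-scale Input estimate, 10 kb local estimate, floor)`
  scaled by library size, with raw p ≤ 0.01 plus a minimum IP/Input fold
  of 2 for reported peaks (`call_peaks()`, `window_scan()`).
* **QC** — strand cross-correlation with fragment-length estimation
  (`cross_correlation()`) and qPCR-style locus enrichment ratios
  (`locus_enrichment_ratio()`).
* **Attribution** — strand-aware classification of each peak
  (unequivocal / divergent / internal promoter / intragenic / excluded)
  from neighbour-gene direction, distance, and TSS containment
  (`classify_peak()`, `summarize_annotations()`, `join_prior_evidence()`).
* **Motif analysis** — −10-anchored alignment (−20..+1), position
  frequencies, IUPAC consensus over −17..−6, and composite σ^S determinant
  scoring (`build_consensus()`, `score_sigmaS_features()`).
* **Simulation** — circular toy genomes with planted binding sites
  (sonication fragments 100–400 bp, configurable enrichment fold, σ^S- or
  σ^70-type promoter sequences) and exact ground-truth labels
  (`generate_genome()`, `simulate_libraries()`).
* **Fixtures** — the published *E. coli* Eσ^S binding-site tables as
  machine-readable data (`load_fixture()`, `fixture_report()`).

## Worked example

Reproduce the published binding-site accounting from the packaged tables
(every number is recomputed by re-running attribution, not read off):

```r
library(sigchip)
str(fixture_report())
#> List of 11
#>  $ n_promoter              : int 63
#>  $ n_unequivocal           : int 50
#>  $ n_divergent             : int 13
#>  $ n_internal              : int 2
#>  $ n_intergenic            : int 61
#>  $ n_intragenic_or_excluded: int 15
#>  $ pct_nonpromoter         : num 19
#>  $ n_unequivocal_flagged   : int 27
#>  $ n_total_flagged         : int 36
#>  $ n_category_matches      : int 63
#>  $ total_called            : int 78
```

63 of 78 peaks overlap promoters (61 intergenic, 2 internal to a host
ORF); 50 attribute unequivocally to one gene and 13 lie between divergent
genes; 27 unequivocally attributed genes (and 36 genes overall) had prior
evidence of rpoS dependence; 19% of the call is non-promoter.

Simulate an experiment and run the full chain:

```r
p <- sim_params(genome_length = 200000, n_genes = 40, n_sites = 10,
                depth = 100000, seed = 42)
g     <- generate_genome(p)
libs  <- simulate_libraries(g, g$sites, p)
ip    <- coverage_from_fragments(libs$ip, p$genome_length)
input <- coverage_from_fragments(libs$input, p$genome_length)

peaks <- call_peaks(ip, input)
head(peaks, 3)
#>   chrom start   end p_value enrichment summit
#> 1   sim  2601  3200       0   4.270842   2882
#> 2   sim  6751  7350       0   4.859442   7034
#> 3   sim 12701 13300       0   4.177771  12987

table(annotate_peaks(peaks, g$annotation)$context)
#> promoter_unequivocal
#>                   10

build_consensus(g$sites$promoter_sequence)$consensus
#> [1] "NNNNCCNNNCNT"

cross_correlation(libs$ip, p$genome_length)$fragment_length_estimate
#> [1] 200
```

All 10 planted sites come back as exactly one peak each, attributed to the
correct gene; the consensus over the ten planted σ^S-type promoters shows
the fixed determinants (−13C/−12C, −8C, −6T) against an otherwise random
background; the cross-correlation shift sits at the fragment scale.

`run_pipeline(config)` orchestrates simulate → call → annotate → motif →
QC from a YAML config (defaults echoed into
`<out_dir>/effective_config.yaml`), writing FASTA/GFF3/BED/bedGraph/TSV
outputs with provenance headers. A thin command-line wrapper lives at
`inst/cli/sigchip.R`.

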