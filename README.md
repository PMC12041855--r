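# rg4dyn

Transcriptome-wide RNA G-quadruplex (rG4) dynamics from
reverse-transcription-stop profiling, with translatome integration — for
researchers studying RNA structure in low-input systems such as mammalian
oocytes.

rG4s are four-stranded structures of stacked guanine tetrads. On stored
maternal mRNAs they are enriched in untranslated regions, are removed
during oocyte meiotic maturation (GV → MII), and suppress translational
efficiency while present; stabilizing them with a small-molecule ligand
(e.g. BYBX) blocks both the removal and the maturation-coupled
translational switch. `rg4dyn` implements the full analysis chain for
such experiments and validates every stage by parameter recovery on a
built-in synthetic-data generator with known ground truth.

## What it computes

- **RT-stop peak calling.** An antibody-captured rG4 terminates reverse
  transcription, so rG4 positions are single-base pileups of read 5' ends.
  After PCR deduplication and 10 nt stranded binning, a treatment bin
  (BG4 library) is called against the IgG control when

  `P(X >= treat; lambda) <= 0.05` and `treat / lambda >= 2`,

  with the Poisson background
  `lambda = max(control_bin, local means at 200 nt / 2 kb, genome floor)`
  scaled to treatment depth. Significant bins merge into peaks with a
  summit at the maximal bin.
- **Quantification.** Per-region densities
  `RPKM = reads x 10^9 / (L_region x total_mapped)` over 5'UTR / CDS /
  3'UTR via exact exon-aware coordinate mapping; TSS/TES metaprofiles and
  peak-centred matrices; canonical PQS scanning
  (`G{3,}(N{1,7}G{3,}){3}`) and 6-mer enrichment of peak sequences.
- **Dynamics.** Condition-specific/shared rG4 transcript sets
  (hypergeometric overlap test) and removal-blockade categories from the
  removal-retention ratio
  `rho = (d_BYBX - d_DMSO) / (d_GV - d_DMSO)` (not affected / partially /
  completely blocked at 0.25 / 0.75).
- **Translatome.** Spike-in-normalized expression
  (`FPKM = count x 10^9 / (L x E_spike)`), translational efficiency
  `TE = RPF / mRNA`, strict 2-fold change classes, rG4 x TE quadrants,
  and RBP binding-change classes from IP/input intensities.
- **Synthetic data.** A seeded generator planting canonical PQS sites
  with condition-dependent foldedness, RT-stop libraries with a
  configurable enrichment over uniform background plus PCR duplicates,
  spike-in-bearing mRNA/RPF counts in which UTR rG4 load suppresses TE,
  and RBP intensity tables with planted classes.

## Worked example

Simulate a small study, call peaks at GV against IgG, and check recovery
against the generator's truth:

```r
library(rg4dyn)

cfg   <- sim_config(seed = 42, n_transcripts = 40, n_sites = 25,
                    lace_depth = 2e5)
sim   <- simulate_transcriptome(cfg)
bg4   <- deduplicate(simulate_lace_reads(sim, cfg, "GV", "BG4"))
igg   <- deduplicate(simulate_lace_reads(sim, cfg, "GV", "IgG"))
peaks <- call_peaks(coverage(bg4, sim$catalog),
                    coverage(igg, sim$catalog))
peaks[1:3, c("chrom", "strand", "summit", "fold_enrichment", "p_value")]
#>      chrom strand summit fold_enrichment p_value
#> 1: chrT001      -   3255        19.09321       0
#> 2: chrT002      +   2685        15.54061       0
#> 3: chrT003      +    935        78.21224       0

table(annotate_peaks(peaks, sim$catalog)$feature)
#>      cds upstream     utr3     utr5
#>        4        1        7       13
```

Each peak summit is the binned RT-stop position; `fold_enrichment` is the
treatment count over the scaled control background at the summit. The
feature table shows the 5'UTR-skewed placement the generator plants. All
25 planted sites are recovered by a summit within ±15 nt of the true stop
(25 peaks total, none spurious):

```r
st  <- sim$truth$sites
hit <- sapply(seq_len(nrow(st)), function(i)
  any(peaks$chrom == st$chrom[i] & abs(peaks$summit - st$stop_gpos[i]) <= 15))
sum(hit)
#> [1] 25
```

## The analysis workflow

`analysis/` contains the staged study as numbered scripts, each a thin
driver over the package that writes its tables under `results/analysis`:

```sh
Rscript analysis/01_simulate.R     # toy transcriptome + read libraries
Rscript analysis/02_call_peaks.R   # dedup, coverage, peaks, annotation
Rscript analysis/03_quantify.R     # metaprofiles, densities, PQS, k-mers
Rscript analysis/04_dynamics.R     # transcript sets, removal categories
Rscript analysis/05_translatome.R  # FPKM, TE, classes, RBP
Rscript analysis/06_report.R       # aggregate report + truth comparison
```

Set `RG4DYN_SEED` to change the seed. `run_pipeline()` performs the same
chain in one call and is byte-deterministic given the configuration.

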