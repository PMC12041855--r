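---
title: "Methods: RT-stop rG4 profiling, dynamics, and translatome integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RT-stop rG4 profiling, dynamics, and translatome integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rg4dyn)
```

## The problem this package addresses

RNA G-quadruplexes (rG4s) are four-stranded structures formed by stacked
guanine tetrads. In transcriptionally silent oocytes they sit on stored
maternal mRNAs — enriched in untranslated regions — and are largely removed
during meiotic maturation (germinal vesicle, GV, to metaphase II, MII);
stabilizing them pharmacologically (e.g. with the rG4-selective ligand
BYBX) blocks that removal and suppresses the translational activation that
normally accompanies maturation. `rg4dyn` implements the complete
computational chain for studying this: detecting rG4 positions from
reverse-transcription-stop (RT-stop) sequencing of antibody-captured
complexes (BG4 antibody versus IgG isotype control), quantifying rG4
density along transcript regions, classifying occupancy changes across
stages and treatments, and integrating the result with spike-in-normalized
ribosome-profiling translatomes.

Everything runs on data from a built-in synthetic generator with known
ground truth, so each stage is validated by parameter recovery rather than
by eyeballing. The generator is a first-class module: its defaults define
the study conditions all recovery tests run under.

## Signal model and peak calling

An RT-stop library records, for every sequenced fragment, the genomic 5'
end of the read — the base where reverse transcription halted. A folded
rG4 bound by antibody terminates reverse transcription at its 3' edge, so
rG4 positions appear as single-base pileups of read 5' ends on the
transcript's strand. The caller:

1. **Deduplicates** on the key (chromosome, strand, 5' position, length) —
   the standard PCR-duplicate key for single-end data. Stacked genuine
   stops survive because fragmentation varies the 3' ends.
2. **Bins** 5' ends into 10 nt stranded bins.
3. Tests each treatment bin against a Poisson background
   `lambda = max(c_raw, c_slocal, c_llocal, floor) x (T/C)` where `c_raw`
   is the control bin, `c_slocal`/`c_llocal` are local control rates over
   200 nt and 2 kb windows, `T/C` scales control to treatment depth, and
   `floor = T x bin / genome_size`. A bin is significant iff
   `P(X >= treat; lambda) <= 0.05` **and** fold enrichment
   `treat/lambda >= 2` (both cutoffs uncorrected and exposed; a BH
   q-value is emitted for information only).
4. **Merges** significant bins within 3 bins of each other and reports the
   leftmost maximal-treatment bin as the summit.

Two details of the local background deserve explanation, because they are
where a naive implementation fails. First, the raw control bin alone is a
one-observation Poisson estimate; its downward fluctuations would dominate
the test, so window averages are required (the same reason sliding
local-lambda callers average over 1-10 kb). Second, on any genome where
expression is blocky — and a desk-scale toy genome is extremely blocky —
*centered* window means are diluted by unexpressed neighbours at block
edges, which is precisely where treatment noise then clears the bar. We
therefore take, at each scale, the larger of the left-flank and
right-flank means computed **over occupied (nonzero) bins only**, with the
centre bin excluded so a single-bin signal cannot inflate its own
background. Empty neighbourhoods contribute nothing and the genome-wide
floor takes over. Calling is strand-aware throughout, because the assay
is stranded.

## Quantification

- **Region densities** (5'UTR / CDS / 3'UTR / full) count deduplicated
  read 5' ends mapped through the exon structure into mature-transcript
  coordinates, as `RPKM = reads x 10^9 / (region_length x total_mapped)`.
  The total is the per-sample deduplicated read count. Reads overlapping
  several transcript models count in each (documented limitation; there is
  no EM rescue). For *dynamics* analyses the density can be restricted to
  reads inside a reference peak set (`region_density(..., peaks = )`):
  raw library background is condition-independent and would otherwise
  mask the condition contrast in the full-transcript value.
- **Metaprofiles** average depth-normalized signal (per 10^7 mapped
  reads) over anchors (TSS, TES, peak centres), reversing minus-strand
  windows so the axis is always 5'→3'. The peak-centred matrix is the
  same computation kept per-row and sorted by row mean.
- **PQS scanning** uses the canonical pattern `G{3,}(N{1,7}G{3,}){3}`
  (loops 1-7 nt, T and U equivalent), greedy and non-overlapping left to
  right. Motif discovery is deliberately replaced by this regex plus a
  6-mer log2 enrichment of peak-upstream sequences over a caller-supplied
  background (we use shuffled sequences): deterministic, testable, and
  sufficient to verify that called peaks are G-rich.

## Dynamics classification

A transcript is *rG4-containing* in a condition iff at least one called
peak summit lies in its exons on the same strand (an any-overlap rule is
available). Two-condition memberships give the standard Venn clusters;
overlap significance is a hypergeometric upper tail, the standard test
for set overlap against a universe.

Removal blockade is classified from three density columns (reference
stage GV, treated stage + vehicle, treated stage + ligand). For
transcripts rG4-positive at GV in which removal occurred
(`d_GV >= 2 x d_DMSO` after pseudocounting), the removal-retention ratio

`rho = clamp((d_BYBX - d_DMSO) / (d_GV - d_DMSO), 0, 1)`

measures how much of the normally-removed signal the ligand retained:
`rho <= 0.25` not affected, `rho >= 0.75` completely blocked, otherwise
partially blocked. The 0.25/0.75 cutoffs are a design choice that makes
three non-degenerate categories; they are surfaced in the configuration
and echoed in all outputs. Because constant background cancels in both
the numerator and denominator, `rho` is insensitive to the background
level; the classification is also exactly invariant to rescaling all
three columns.

## Translatome

Expression is spike-normalized: `FPKM_t = count_t x 10^9 / (L_t x E_s)`
with `E_s` the total spike-in-mapped count of the sample. Normalizing to
the spike-in total rather than the library total preserves *absolute*
scale across samples — a global shift in cellular mRNA content changes
every library-normalized quantity but cancels here, because any
per-sample depth nuisance multiplies transcript counts and `E_s` alike.
(A median-of-ratios alternative over spike rows is available behind a
flag.) RPF (ribosome-protected fragment) libraries are quantified over
CDS length, since footprints are CDS events; a full-length flag exists.

Translational efficiency is `TE = (RPF_FPKM + 0.1) / (mRNA_FPKM + 0.1)`;
transcripts with mRNA FPKM below 1 everywhere are flagged low-confidence
rather than dropped. Fold-change classes use strict inequalities — "more
than 2-fold" means a ratio of exactly 2 is unchanged. rG4-by-TE
integration labels each transcript by (rG4 up/down/flat, TE
up/down/unchanged) and emits the headline sets (TE-down with rG4-up, and
their intersection with the maturation-activated translatome).

RBP (RNA-binding protein) binding classes from IP/input intensity
tables: proteins without input signal are excluded; bound-under-mock but
zero-under-treatment is completely blocked; otherwise the IP ratio
thresholds 0.5/2 give down/unchanged/up.

## The synthetic generator: what it emulates and what it does not

One toy chromosome per transcript (default 100), intergenic pads of
2.5 kb, 1-3 exons, mean region lengths 200/600/400 nt (5'UTR/CDS/3'UTR),
each drawn uniformly in 0.5-1.5x the mean. All background sequence is
free of G- and C-runs by construction, so the only PQS on either strand
are the 50 planted sites, allocated 45%/15%/30%/10% to
5'UTR/CDS/3'UTR/upstream — a 5'UTR-enriched per-kilobase density, the
pattern the region-density stage must reproduce. Planted sites keep at
least 60 nt apart so that two stops never fall inside one merge window;
recovery is scored summit-to-truth within ±15 nt, which cannot credit one
summit to two sites.

Libraries: background read 5' ends are uniform over each transcript at a
rate proportional to abundance (lognormal, sdlog 0.5 — a moderate dynamic
range; see below), plus 2% genome-wide noise in both libraries. In the
treatment library each site's stop point receives Poisson extra reads
with mean `mu x 10 x lambda_fold x f`, where `mu` is the transcript's
per-base background, `lambda_fold = 50` is the enrichment of a fully
folded site, and `f` is the site's foldedness in the condition (defaults:
GV 1, MII+vehicle 0.1, MII+ligand 0.9). No published estimate pins the
real enrichment magnitude; 50 is a free choice and is echoed into every
report. Read lengths are uniform over 20-170 nt (insert-size range of a
250-500 bp library), and stops jitter by ±2 nt around the site edge.
These two choices matter more than they look: the deduplication key is
(position, length), so the number of distinct (position, length) pairs
bounds how many stacked stop reads survive deduplication. Variable
lengths and slight positional jitter give the stop pile a realistic
post-deduplication dynamic range; with fixed-length, zero-jitter reads,
deduplication would crush every site to a handful of records. Likewise
the moderate abundance spread keeps the most abundant transcripts from
saturating this capacity and pushing site fold-enrichment below the
calling cutoff.

True TE per transcript is
`log2 tau = tau0 - alpha x sum(f, 5'UTR sites) - beta x sum(f, 3'UTR sites)`
with `tau0 ~ N(0, 1)` (log2), `alpha = 2`, `beta = 1`: a fully folded
5'UTR site suppresses TE four-fold, a 3'UTR site two-fold, consistent
with the strong repression reporter assays show for 5'UTR quadruplexes
and the weaker 3'UTR effect. mRNA counts are Poisson in
`abundance x length`, RPF counts in `abundance x tau x CDS length`, both
multiplied by a lognormal per-sample depth nuisance (sdlog 0.3) that the
spike normalization must cancel; 20 spike species follow a 2^k
concentration ladder at 5% of library mass. A negative-binomial
dispersion knob exists (default off — Poisson).

What the generator does **not** emulate: sequencing errors, fragment-length
biology, isoform ambiguity (one isoform per gene), mappability, real
spike-in catalog concentrations, per-site foldedness heterogeneity within
a condition, or any dependence of mRNA abundance on condition (maternal
decay is deliberately absent so expression contrasts isolate TE). Passing
recovery tests therefore demonstrates that the *estimators* are correct
under the stated statistical model, not that the model captures every
property of real libraries. One visible consequence: with a single
foldedness value per condition, sites at the treated stage are either all
above or all below the detection threshold, so synthetic Venn clusters do
not show the mixed specific/shared structure real data shows; removal is
read off the in-peak density change instead.

## Numerical choices and degenerate inputs

- Coordinates are 0-based half-open internally; GTF (1-based closed)
  converts on ingest; the minus-strand read 5' end is the last base of the
  alignment interval.
- Summit ties break to the leftmost maximal bin; peak-matrix row ties
  break by id.
- Pseudocounts: 0.01 (density ratios, removal), 0.1 FPKM (TE). A zero
  control library total or zero spike-in total is an error, never a
  silent fallback. `TE(0, 0)` is 1 and flagged low-confidence.
- Zero-length regions yield `NA` density, not 0.
- Determinism: every stochastic step seeds a local RNG stream derived
  from the configuration seed and the stage label, so any two runs with
  one configuration are byte-identical, and stages can run independently
  without consuming each other's randomness.

## Problem sizes

The test suite and the acceptance script run the full study at the
default conditions (100 transcripts, 50 sites, 5x10^5 background reads
per RT-stop library; 500 transcripts and 10^6 fragments for the
translatome recovery), and the determinism check at a reduced 25
transcripts / 10^5 reads — sizes chosen so the whole verification runs
on a laptop-class single core in a few minutes while keeping every
recovery margin wide.

## Known limitations

- Per-transcript read assignment counts a read in every overlapping
  model; quantification on heavily overlapping annotations inflates
  densities.
- The peak caller is not a reimplementation of MACS2: no model building,
  no fragment-size estimation, no broad peaks. It is a transparent
  single-pass Poisson rule chosen to be brute-force verifiable.
- The Venn overlap test is hypergeometric; it assumes exchangeable
  transcripts and a well-defined universe (the catalog).
- The removal-retention ratio presumes densities on a common scale
  across conditions (equal-depth normalization upstream).
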