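# dupHiC

**Duplication-aware Hi-C: multi-mapping read rescue, TAD boundary calling
and viewpoint profiling across tandem segmental duplications.**

## The problem

Standard Hi-C pipelines keep only uniquely mapping reads. Over a large
tandem segmental duplication — such as the 18 kb low-copy repeat inside the
complement receptor gene *CR1*, repeated 1–3 times per allele — every read
is ambiguous among the copies and gets discarded, leaving a hole in the
contact map. When a topologically associating domain (TAD) boundary lies
*inside* the repeat, that hole removes exactly the evidence needed to
localize it. dupHiC is for analysts who need chromatin architecture at such
loci: it rescues the multi-mapping reads probabilistically and carries the
analysis through to boundary calls, viewpoint profiles and CTCF anchor
orientation, exercised end-to-end on a self-contained synthetic locus so
no external data is required.

## The method

For each multi-mapping read pair with candidate bin pairs
*k = 1, 2, …* at genomic distances *d_k*, the posterior probability that
candidate *k* is the true origin is computed iteratively as

> π_k ∝ P(d_k) · (L_k + c)

where **P(d)** is a distance-decay prior — mean contact counts of uniquely
mapping reads per bin-pair at each distance, spline-smoothed in log–log
space and normalized — **L_k** the current contact count (uni-reads plus
fractional multiread mass) in the (2w+1)×(2w+1) bin-pair neighbourhood of
candidate *k*, and **c** a pseudocount. Posteriors are renormalized per
read and the fractional counts refreshed synchronously each sweep until
convergence. The posteriors are then either **accumulated as fractional
contact counts** (mass is conserved exactly: #uni + #multi) or used for a
**stringent allocation** that keeps a read only when its best candidate
reaches a 0.99 posterior score.

On the rescued matrix, first-level TAD boundaries are called by spectral
segmentation (degree-normalized Laplacian of windowed contact graphs,
contiguous dynamic-programming grouping, silhouette-selected group count)
at 25 kb resolution; virtual-4C profiles are extracted from bp viewpoints;
and CTCF motif hits (log-odds PWM scan, both strands) classify each TAD's
anchors as convergent, tandem or divergent.

## Worked example

```r
library(dupHiC)

layout <- build_layout()                     # 1 Mb synthetic locus
layout
#> <region_layout> 1e+06 bp / 5000 bp bins (200 bins)
#>   genes: C4BPB, C4BPA, CD55, CR2, CR1, CR1L, CD46
#>   duplication: 18000 bp unit x 2 copies at [450000, 486000)
#>   planted boundaries (bp): 477000

sim <- simulate_contacts(layout, n_reads = 100000, seed = 7)
res <- rescue_reads(sim$reads, n_bins = layout$n_bins,
                    bin_size = layout$bin_size)
res
#> <rescue_result> mode=fractional, uni=95005, multi=4995, kept=4995, mass=100000

seg <- call_tads(coarsen(res$matrix, factor = 5))    # 25 kb resolution
seg
#> <tad_segmentation> 2 TADs over 40 bins at 25000 bp; interior boundaries: 19

annotate_boundaries(seg, layout)
#>   boundary_bp coarse_bin          label    score
#> 1           0          0    region edge       NA
#> 2      475000         19 CR1,dup_copy_2 4.045731
#> 3     1000000         40    region edge       NA

prof <- virtual_4c(res$matrix, "chrS:520000-525000", smooth_window = 1)
round(side_mass_fraction(prof, layout$tad_boundaries_truth), 3)
#> [1] 0.934
```

Reading the output: 5% of the simulated reads are ambiguous between the
two duplication copies; after rescue the matrix mass equals the full
100,000 reads, with the duplication interior (which has zero uni-read
coverage) repopulated by fractional counts. The TAD caller places the
single interior boundary at coarse bin 19 (475–500 kb), the bin containing
the planted boundary at 477 kb — inside the second duplication copy of
*CR1*, as the annotation reports. A viewpoint 43 kb downstream of the
boundary keeps 93% of its interaction mass on its own side, the signature
of a domain boundary immediately upstream.

A command-line front end covering every stage
(`simulate`, `rescue`, `tads`, `v4c`, `motifs`, `quant`, `run`) is
installed at `inst/scripts/dup-hic`:

```sh
dup-hic run --seed 7 --out out/           # full pipeline + manifest
dup-hic quant --assay ddct --params 24,20
```

The package also implements the downstream quantification arithmetic —
comparative-Ct expression, ChIP percent input, nuclease-protection
accessibility/occupancy, dual-luciferase normalization and the pooled
t-test — as pure, vectorized functions (see `?relative_expression` and
friends).

## The methods vignette

`vignettes/duplication-aware-hic.Rmd` documents the model and its
assumptions, every tunable parameter with its default and rationale, what
the synthetic generator does and does not emulate, numerical choices
(tolerances, tie-breaks, degenerate inputs) and known limitations.
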