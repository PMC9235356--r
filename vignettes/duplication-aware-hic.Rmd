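---
title: "Duplication-aware Hi-C: methods and design notes"
author: "dupHiC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Duplication-aware Hi-C: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupHiC)
```

## The problem

Large tandem segmental duplications are invisible to standard Hi-C
processing: a sequencing read arising from any copy of the repeat aligns
equally well to every copy, is flagged as multi-mapping, and is discarded.
The consequence is a hole in the contact map — and when a topologically
associating domain (TAD) boundary happens to sit *inside* the repeat, the
hole swallows exactly the evidence needed to localize it. The canonical
example is the 18 kb low-copy repeat inside the complement receptor gene
*CR1* (present in 1–3 tandem copies per allele), which harbours an
inter-TAD boundary of the RCA gene cluster and repeated reverse-orientation
CTCF sites in every copy.

dupHiC implements the full desk-scale analysis around this situation:

1. a **synthetic-region generator** producing read pairs with the
   statistical structure the analysis assumes (power-law distance decay,
   boundary insulation, duplication-induced mapping ambiguity);
2. **multiread rescue** — a distance-decay spline prior estimated from
   uniquely mapping reads, iterative per-read posteriors driven by local
   contact counts, and either fractional-count accumulation or a stringent
   whole-read allocation at a 0.99 posterior score;
3. a **spectral TAD caller** operating on the rescued matrix at coarse
   (25 kb) resolution;
4. **virtual-4C** viewpoint profiles and bedGraph export;
5. **CTCF motif scanning** with strand, and classification of TAD anchor
   orientation (convergent / tandem / divergent);
6. the **assay arithmetic** used downstream of such analyses
   (comparative Ct, percent input, nuclease-protection accessibility and
   occupancy, dual-luciferase normalization, pooled t-test).

## The synthetic region

`build_layout()` describes a 1 Mb region binned at 5 kb containing seven
tandem genes (named after the RCA members they emulate), an 18 kb
duplication unit repeated twice starting at 450 kb, and a planted TAD
boundary at the midpoint of the second copy (477 kb) — echoing a boundary
refined to an intron in the middle of the repeat. Every duplication copy
carries a reverse-orientation CTCF site; a forward site near the region
start and a reverse site near the region end give both TADs convergent
outer anchors, and a forward site just downstream of the duplicated block
anchors the second TAD.

`simulate_contacts()` draws each read pair's true bin pair with probability
proportional to

$$P(i, j) \propto (d + 1)^{-\alpha}\, s^{\,b(i,j)}, \qquad d = |i - j|,$$

where $\alpha$ is the decay exponent, $s \in (0, 1]$ the insulation factor
and $b(i,j)$ the number of planted boundaries between the bin midpoints.
Self-pairs ($d = 0$) are excluded, mirroring the short-range filtering of
standard Hi-C pipelines. Applying $s$ once per crossed boundary (rather
than once whenever any boundary is crossed) is the standard block model;
the two are identical for the single-interior-boundary default layout.

Read ends are then placed uniformly *within* their true bin at bp
resolution. An end that falls inside the duplicated block is ambiguous
among the homologous bp positions in every copy (shifts by whole
duplication units); candidates are the binned images of those positions.
Working at bp level keeps the homology exact even though the 18 kb unit is
not a multiple of the 5 kb bin. Copies are exact duplicates — the worst
case for mappability; sequence divergence between copies is out of scope.

Defaults are fixed once: $\alpha = 1.0$ (the canonical contact-probability
power law at the sub-Mb scale), $s = 0.2$, 100,000 reads. Insulation
strength between real TADs is not a measured quantity here; 0.2 produces
clear but not caricatural cross-boundary depletion. All randomness flows
through R's default Mersenne-Twister generator from a single seed, so
fixtures are byte-identical across runs and platforms.

**What the generator does not emulate:** restriction-fragment geometry,
ligation artefacts, trans contacts, copy-number differences between
homologous chromosomes, mapping errors outside the duplication, and
coverage biases (GC, mappability gradients). Passing tests therefore
demonstrate correctness of the estimators under the assumed sampling
model, not robustness to every artefact of real libraries.

## Multiread rescue

Uniquely mapping reads are binned (`bin_uni_reads()`) and used to fit the
distance-decay prior (`fit_distance_prior()`): the mean count per
admissible bin pair at each distance $d \ge$ `min_d` is smoothed by
`stats::smooth.spline` in log–log space, exponentiated, floored at
$\varepsilon = 10^{-12}$ and normalized over the distance grid. The floor
keeps posteriors defined at unobserved distances; `min_d = 2` bins excludes
self- and adjacent-bin artefacts. The prior is fitted once, on uni-reads
only; refitting after multireads are incorporated is a conceivable
variant, but the uni-read fit is reproducible and unbiased by the
allocation it feeds.

`allocate_multireads()` then iterates, for every multiread and candidate
bin pair $k$ at distance $d_k$:

$$\pi_k \;\propto\; P(d_k)\,\bigl(L_k + c\bigr),$$

where $L_k$ is the summed current count (uni-reads plus the current
fractional multiread mass) in the $(2w+1)\times(2w+1)$ bin-pair
neighbourhood centred on candidate $k$, clipped at the matrix edge, and
$c$ is a pseudocount. Posteriors are renormalized per read. Design
choices, all exposed as arguments:

* **Neighbourhood half-width `w = 2`** (a 25 kb window at 5 kb bins):
  "local" counts need a scale; two bins balances locality against noise.
* **Pseudocount `c = 0.5`**: zero-coverage candidates — precisely the
  duplication interior on the first sweep — retain prior-driven mass
  instead of being annihilated by an empty neighbourhood.
* **Jacobi-style sweeps**: fractional contributions are refreshed
  synchronously from the new posteriors after each sweep, never read by
  read, so the result is independent of input order. The first sweep sees
  uni-read counts only.
* **Convergence**: largest absolute posterior change below `tol = 1e-4`,
  cap of 50 sweeps; on the default layout convergence takes ~10 sweeps.

`accumulate_fractional()` adds each read's posterior mass at its
candidates, so total mass is exactly #uni + #multi — conservation holds
for converged and non-converged states alike, and is asserted to 1e-9 in
the tests. `apply_stringent_filter()` instead assigns a read wholly to its
maximum-posterior candidate iff that posterior is $\ge$ 0.99 (ties at the
threshold are kept, matching the "greater or equal" convention) and
discards the rest. With *exact* duplicate copies most multireads are
intrinsically symmetric between copies, so the stringent mode keeps only a
small minority (~4% on the default layout) — the expected behaviour for
this worst-case homology, and the reason fractional accumulation is the
default mode.

## Spectral TAD calling

`coarsen()` sum-pools the rescued 5 kb matrix to 25 kb (mass preserved
exactly; a trailing partial bin group is absorbed into the last coarse
bin). `call_tads()` is a re-implementation *in the spirit of* spectral TAD
callers, not a port of any specific tool: sliding windows (40 coarse bins,
stepped by half a window) along the diagonal are segmented by spectral
clustering of the windowed contact graph — symmetrized adjacency,
degree-normalized Laplacian $L = I - D^{-1/2} A D^{-1/2}$, leading
eigenvectors with signs fixed first-nonzero-positive, row-normalized
embedding — followed by an exact contiguity-respecting dynamic-programming
segmentation into $k$ groups (minimum within-segment sum of squares,
minimum TAD size 4 coarse bins = 100 kb). The group count is chosen by the
mean silhouette width over $k \in \{1..5\}$, with $k = 1$ whenever no
split reaches a silhouette of 0.15. Window-level cuts are consolidated by
majority voting over the windows covering each position; cuts closer than
the minimum TAD size are resolved in favour of the better-supported one
(deterministic tie-break: the later cut is dropped). Contacts beyond 200
coarse bins are ignored when building window graphs — irrelevant at this
region scale, a guard for larger inputs.

The call is deterministic for a fixed matrix, invariant to sparse-triplet
insertion order and to positive rescaling of counts. Degenerate inputs: an
all-zero matrix returns a single TAD with a warning; a constant matrix
(structureless complete graph) yields no interior boundary because no
split reaches the minimum silhouette. Only first-level boundaries are
called; nested sub-TADs are out of scope. Note one behaviour worth knowing:
a pure distance-decay (banded) matrix *without* any insulation still
produces low-conductance cuts, so the caller may split it — recovery of a
*planted* boundary should always be judged against its position, as the
tests do (within ±1 coarse bin over 20 seeds).

## Virtual 4C

`virtual_4c()` sums the matrix rows of the bins overlapped by a bp
viewpoint interval and applies a centred moving average (default 3 bins)
with truncated edges. Viewpoint self-bins are reported and flagged, not
zeroed — raw fractional counts are used throughout, with no additional
normalization. The default pipeline viewpoint (chrS:520,000–525,000) sits
~43 kb downstream of the planted boundary, emulating a viewpoint placed in
the gene body downstream of the repeat; on the default layout ~93% of its
profile mass falls on its own side of the boundary, reproducing the
signature of a viewpoint whose interactions are constrained downstream.
Export is 4-column bedGraph (0-based half-open bin intervals,
full-precision values).

## CTCF motifs and anchor orientation

`scan_pwm()` scores every window of a sequence with the summed per-position
log2 odds against the background composition, in bits; the reverse strand
is scored on the reverse complement (implemented by scanning with the
reverse-complemented matrix) and reported at the same forward coordinate.
Windows containing N are skipped; overlapping hits are all reported, since
repeat copies legitimately produce periodic hits. The motif matrix is an
input (tab-separated counts or probabilities, counts normalized with a
pseudocount of 0.25 per cell); the package ships a *synthetic* CTCF-like
14 bp matrix (`inst/extdata/ctcf_motif_synthetic.tsv`) for scanning the
synthetic region — it is a constructed stand-in, not a database motif. The
default threshold of 8 bits is an explicit parameter with no claimed
equivalence to any database's cutoff; at 8 bits a 1 Mb random background
yields a few hundred hits, so tests that need to isolate the planted
consensus sites use a 20-bit threshold.

`classify_anchor_orientation()` labels each TAD from the hits within a
window (default 2 coarse bins) of its boundaries: convergent ("+" at the
left anchor and "−" at the right), divergent (the mirror), tandem
(same-strand at both), otherwise unanchored; convergent takes precedence
when several predicates hold. On the default layout both TADs classify as
convergent and the first TAD's right anchor reports one reverse-orientation
hit per duplication copy.

`synth_region_sequence()` generates the region sequence itself: random
background with the motif consensus planted at every CTCF site and the
first duplication unit copied verbatim onto the remaining copies, so the
repeat is an exact sequence duplication carrying the same motifs.

## Assay arithmetic

The quantification formulas are pure functions over Ct values and
luminescence readings:

* relative expression $2^{-\Delta Ct}$, fold change $2^{-\Delta\Delta Ct}$;
* percent input $100 \cdot 2^{(Ct_{input} - \log_2(1/f)) - Ct_{IP}}$ with
  input fraction $f$ (default 0.01, always an explicit parameter);
* nuclease protection: retained fraction $2^{-(Ct_{dig} - Ct_{undig})}$;
  accessibility $1 - \mathrm{ret}(target)/\mathrm{ret}(control)$ and MNase
  occupancy $\mathrm{ret}(target)/\mathrm{ret}(control)$, both clipped to
  $[0,1]$ with a warning (1.0 = fully compacted nucleosomes). The exact
  normalization arithmetic of protection assays varies between labs; the
  retained-fraction ratio used here is a parameterized interpretation, not
  a universal standard.
* dual luciferase: construct firefly/Renilla ratio over the control ratio;
* Student's unpaired pooled-variance t-test via `stats::t.test(var.equal =
  TRUE)` with explicit degenerate handling (identical constant groups give
  $t = 0, p = 1$; constant groups with unequal means are an error).

Replicates are averaged on the Ct scale before exponentiation
(`summarise_ct()`), with the SEM propagated to the transformed scale by
the delta method. All Ct-based quantities are invariant to adding a
constant to both members of a comparison pair.

## Problem sizes and reproducibility

The shipped analyses use a 200-bin (1 Mb / 5 kb) region with 100,000 reads
per simulation (200,000 for decay-recovery checks), 10–20 seeds per
property; a full simulate→rescue→call cycle takes well under a second, so
the whole suite and the acceptance script each run in about a minute on a
single CPU. `run_pipeline()` writes a manifest with the resolved
parameters, seed and MD5 checksums of every artifact; re-running an
identical configuration reproduces byte-identical files.

## Known limitations

* The rescue model combines the prior and local counts as a product; the
  precise functional form used by published multiread-rescue pipelines is
  not printed in their method summaries, so this form is an interpretation
  consistent with their description, validated here against its own
  contract (exact formula equivalence, conservation, monotonicity).
* The TAD caller claims recovery of planted truth on synthetic data, not
  equivalence with any published caller's output on real data.
* Exact repeat copies make per-copy contact assignment fundamentally
  ambiguous; fractional counts recover the *aggregate* architecture
  (coverage, boundary position) but cannot resolve copy-specific loops.
* Matrix balancing (ICE/KR) is deliberately absent: the rescue operates on
  raw counts, and balancing would break the mass-conservation contract.
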