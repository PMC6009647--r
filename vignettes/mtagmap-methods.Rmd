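---
title: "Methods: simulating and mapping methyltransferase-labeled DNA"
author: "mtagmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and mapping methyltransferase-labeled DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtagmap)
```

# Overview

DNA methyltransferases can be redirected to deposit a fluorophore (instead
of a methyl group) at every occurrence of their short recognition motif —
for M.TaqI, the palindromic 4-mer TCGA.  Imaged on stretched,
surface-deposited molecules, the fluorophore positions form a sequence
barcode.  `mtagmap` implements the analysis chain of such an experiment and
a matching synthetic-data generator with full ground truth, so every stage
can be validated quantitatively:

1. **Reference maps** (`find_sites`, `in_silico_pcr`): motif site lists on a
   named sequence, in-silico PCR to extract amplicons, BED/FASTA plumbing.
2. **Simulation** (`simulate_molecules`, `simulate_plasmid_field`,
   `simulate_movie`, `simulate_kinetics`): labeled molecules, two-channel
   plasmid fields, photobleaching movies, and kinetic time courses.
3. **Localization and counting** (`bleaching_localization`,
   `reconstruct_masks`, `count_labels`).
4. **Alignment** (`align`, `align_best_orientation`): stretch-tolerant
   monotone matching of label positions to the reference map.
5. **Consensus and off-target statistics** (`place_labels`,
   `remove_dual_strand`, `build_consensus`, `offsite_stats`).
6. **Summary statistics** (`fit_pseudo_first_order`, `poisson_zero_bound`,
   `fold_change`, `titration_regression`).

# The generative model

A molecule of length $L$ bp carries:

* **On-site labels.**  Each of the $S$ motif sites is labeled independently
  with probability $p_\mathrm{site}$.  Because the motif is palindromic, a
  site has two modifiable strands but normally carries at most one
  fluorophore; in double-strand mode a *labeled* site carries a second
  fluorophore with probability $p_\mathrm{second}$, offset by the motif
  width.  We read "the second strand is also labeled" as conditional on the
  first label; under this reading the dual-strand removal rule restores the
  single-strand per-site expectation exactly, which is what the removal
  stage is for.
* **Off-target labels.**  A homogeneous Poisson process with density
  $\rho$ labels/kb, uniform along the molecule.
* **Localization noise.**  True bp positions are perturbed by
  $\mathcal{N}(0, \sigma_\mathrm{loc}^2)$ *in bp, before* stretch
  conversion, so $\sigma_\mathrm{loc}$ is quoted in sequence units.
* **Stretching.**  Physical position is
  $x_\mathrm{nm} = x_\mathrm{bp} \cdot 0.34\,\mathrm{nm/bp} \cdot s$ with a
  single per-molecule stretch $s \sim \mathcal{N}(\bar s, (\bar s\,
  \delta)^2)$ truncated at $\pm 2\delta$ (a uniform option is provided,
  since quoted stretch "variations" can be either a spread or a hard band).
  Within-molecule stretch fluctuation is folded into
  $\sigma_\mathrm{loc}$; this matches the aligner's single-stretch search.
* **Orientation.**  Each molecule is mirrored with probability
  $f_\mathrm{flip}$ (default 0.5; deposition does not fix polarity).

Defaults (`sim_config()`): $p_\mathrm{site} = 0.92$, $\rho = 0.46$/kb,
$\sigma_\mathrm{loc} = 100$ bp, $\bar s = 1.6$, $\delta = 0.1$ — the combed
5 kb fragment regime; `preset = "plasmid"` switches to $p_\mathrm{site} =
0.63$, $\rho = 0.37$/kb, the plasmid counting regime.  These are derived
from published summary statistics of the underlying experiment and are
defaults, not ground truth.  One master seed feeds deterministically derived
child streams per stage, so fixed-seed runs are bit-identical while stages
stay independent.

What the generator does **not** emulate: optical aberrations and drift,
chromatic offsets between channels, fluorophore blinking (the label channel
bleaches in a single step; the backbone channel is modeled only as an
accumulated point cloud), DNA fragmentation, and non-uniform stretching
along a molecule.  Tests passing on these simulations therefore validate
the algorithmic chain under the stated statistical model, not instrument-
specific artifacts.

# Bleaching-assisted localization

Overlapping fluorophores separated by less than the diffraction limit are
resolved in time: in the *last* frames of a movie only the longest-lived
emitters remain and are isolated.  `bleaching_localization()` walks
backwards:

1. average the trailing `window` (default 10) frames of the residual movie;
2. detect local maxima above `median + n_sigma * MAD` (default $n=5$; the
   paper-scale algorithm gives no threshold, so it is a logged parameter);
3. least-squares fit a 2D Gaussian (amplitude, subpixel centre, width,
   offset) in an ROI;
4. estimate the bleach frame by a single-step change point on the
   ROI-integrated trace, restricted to frames at or after the current
   window (the emitter demonstrably survived into it — this guards against
   locking onto a brighter neighbour's earlier step);
5. re-fit the amplitude on frames where the emitter is fully on, and
   subtract the fitted PSF from all frames up to the bleach frame;
6. step the window earlier when nothing is found, until the movie start.

Numerical guards: fits that fail to converge, fall below the detection
threshold, or return implausible widths (outside $[0.5, 2.5]\times$ the
nominal PSF sigma) are discarded with a warning; stepless detections away
from the movie end and near-duplicates (within `min_sep`, similar bleach
frame) are treated as subtraction residue.  A robust noise floor of
$0.01\times$ background keeps noiseless test movies from producing
spurious maxima.

Plasmid masks are a 2D histogram of backbone localizations, binarized
(fixed count or Otsu), dilated once, hole-filled, and labeled.  Perimeter is
measured as exposed 4-neighbour pixel edges scaled by $\pi/4$ (exact for
disks), so circularity $4\pi A / P^2$ is $\approx 1$ for plasmids and small
for linear debris; the acceptance filter defaults to circularity $\ge 0.6$
with area bounds (the source experiment states only "circular in
appearance", so both are parameters).  Counting divides total labels inside
accepted masks by the number of accepted plasmids, with
$\mathrm{SEM} = \mathrm{sd}(X)/\sqrt{N}$.

# Stretch-tolerant alignment

Labels are matched to sites by a dynamic program over label index $i$ and
site index $j$ with transitions match / skip-site / skip-label.  A match is
allowed when the converted label lies within `match_width` (default 150 bp)
of the site and scores $1 - |\Delta|/w$ (triangular taper; a flat-score
flag reproduces plain hit counting).  Skipping an interior site costs 0.5,
an extra label 0.25 (in units of the match score; the source algorithm
publishes no penalties, so they are parameters, and the recovery properties
hold across a several-fold penalty range).  Ends are free by default
because molecules are full-length fragments; a fully local mode is
available behind a flag.

The molecule-level transform is a single stretch plus a global offset:
stretch is searched on a grid of 11 values spanning $1.6 (1 \pm 0.1)$,
offsets come from label/site anchor-pair differences (deduplicated, bounded
by `offset_max`).  The grid optimum is then *polished*: offset and stretch
are refit by least squares over the matched anchor pairs and the matching
re-derived once at that transform, which is returned unconditionally.
Adopting the least-squares transform instead of the grid maximum avoids
selecting for configurations that happen to rescue borderline matches, so
matched-count and residual statistics remain unbiased up to the two fitted
parameters per molecule.  Both orientations are aligned and the higher
score kept (ties to forward).  Under the continuous taper, score ties are
measure-zero; remaining ties break toward more matches, with a
deterministic traceback preference (match, then skip-site, then
skip-label).

# Consensus and off-target statistics

Matched labels project exactly onto their site coordinates; unmatched
labels interpolate linearly between the flanking anchor pairs and fall back
to the molecule's affine transform outside the anchors (and for molecules
without matches).  Note that interpolation propagates the anchors' own
localization noise: an interpolated label at relative position $t$ between
two anchors has variance $\sigma^2 (1 + (1-t)^2 + t^2)$.

Palindromic sites labeled on both strands produce a satellite label within
~100 bp of a matched one.  `remove_dual_strand()` applies the published
rule per molecule: for each matched label in coordinate order, at most one
not-yet-removed unmatched label within 100 bp is removed — nearest first by
default (a leftmost-first variant is provided; the published sentence does
not fix the order).  Removal happens before consensus binning; the
alternative (pooled removal after binning) is not what a per-molecule
dual-strand artifact calls for.  The consensus histogram bins non-removed
labels at 50 bp (below the 100–150 bp precision scale).

`offsite_stats()` reports the literal decomposition — unmatched fraction
$U/(M+U)$, density $U/(n L_\mathrm{kb})$, matched labels per site — plus
*truncation-corrected* estimators.  A hard 150 bp match window captures
only $c = 2\Phi(w/\sigma) - 1$ of genuinely on-site labels (86.6% at
$\sigma = 100$ bp), so raw counts misattribute escaped on-site labels to
the off-site class.  With $\sigma$ estimated from the matched residuals by
truncated-normal moment matching — after rescaling the residuals for the
two affine parameters fitted per molecule — the corrected per-site
efficiency is $M/(nSc)$ and the expected escape mass $M(1-c)/c$ is moved
back from the unmatched side.  On simulated cohorts in the default regime
this recovers the generator's efficiency, off-site density and off-site
fraction within the tolerances asserted in the test suite; the residual
$\sigma$ estimate partially absorbs second-order effects (off-site labels
captured by open sites, close-pair cross-matching), which is why the
simpler truncation-only correction is used rather than an explicit
false-match model.  A Kolmogorov–Smirnov test against Uniform$(0, L)$
quantifies whether unmatched labels are position-independent.

# Kinetics and specificity statistics

The labeling time course is pseudo-first-order,
$N(t) = N_\infty (1 - e^{-k' t})$, fitted by nonlinear least squares on the
per-time means (initialized from the max and a log-linear rate estimate,
parameter tolerance $10^{-8}$).  Counts from the generator include the
constant off-target floor, so an optional additive baseline can be fitted;
the two-parameter form mirrors the published model and remains the
default.  The published experiment does not show residuals or name the
fitting procedure; least squares on means is our assumption.

The non-specific binding bound converts a zero-label fraction $f_0$ into a
Poisson rate $\lambda = -\ln f_0$ per molecule, i.e. one fluorophore per
$L_\mathrm{kb}/\lambda$ kb.  With $f_0 = 0.97$ on a 2.6 kb plasmid this
gives 85 kb per fluorophore (the cruder odds form
$L f_0/(1-f_0)$ is exposed as an option).  Site-count titrations are
summarized by ordinary least squares of mean labels on site count: the
slope estimates per-site efficiency, the intercept the off-target labels
per plasmid ("sites plus one" when both are near 1).

# Design choices on genuinely open points

* **Site coordinate convention**: a site's position is the motif start (not
  the modified adenine); the ≤4 bp discrepancy is far below the 100 bp
  precision.  Coordinates are 0-based, intervals half-open, BED on disk.
* **IUPAC codes are rejected**, not expanded: every motif in scope (TCGA,
  GGATG, GCGC, CG) is unambiguous.
* **Alignment mode**: the Smith–Waterman-style dynamic program runs as a
  global alignment with free end-gaps rather than fully local, because
  molecules are full-length PCR fragments; a local mode remains available.
  Whether earlier mapping software of this kind scored inter-label spacing
  ratios rather than absolute positions is an open interpretation; the
  grid-search-with-offset reading is flagged as ours.
* **Stretch variation** is exposed as both truncated-normal (default) and
  uniform, since the published "0.1 variation" does not distinguish a
  spread from a hard bound.
* **Movie stacks** are `(H, W, frames)` arrays (R matrix idiom) written as
  16-bit photon-count TIFFs.
* **Pipeline configs** are YAML with the two presets named
  `"combed-fragment"` and `"plasmid"`; every run writes a manifest (config
  echo, seed, package version) sufficient to reproduce it bit-identically.

# Problem sizes used by the test suite

The suite simulates at the scale of the experiments it mirrors: 180–500
molecules for alignment/off-site recovery, 5000 molecules for closed-form
count checks, 200 kinetic replicates of 8 time points × 300 plasmids, 50
photobleaching movies of 32×32 px × 200 frames (four emitters each), and
20 fields × 50 plasmids for counting bias.  A full synthetic pipeline run
at the 180-molecule scale completes in seconds.

# Known limitations

* The per-site efficiency and off-site corrections assume Gaussian
  localization errors and a known/estimable $\sigma$; heavy-tailed errors
  would bias the capture estimate.
* Orientation recovery degrades for sparsely labeled molecules and for
  nearly symmetric maps; misoriented molecules inflate the off-site class.
* Close site pairs (~100 bp apart, at the localization precision) are
  genuinely ambiguous: a dual-strand satellite of one site can be matched
  to its empty neighbour.  The removal rule does not undo matched labels.
* The localizer assumes single-step bleaching and no blinking; blinking
  fluorophores would be double-counted.
* `in_silico_pcr` requires exact primer matches (no mismatch tolerance).
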