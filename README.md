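# mtagmap

Single-molecule analysis of methyltransferase-directed fluorescent DNA
labeling (optical DNA mapping).

DNA methyltransferases can be repurposed to attach a fluorophore at every
occurrence of their recognition motif — for M.TaqI, the palindromic 4-mer
TCGA.  Imaged on stretched, surface-deposited molecules, the label
positions form a sequence barcode; on plasmids, per-molecule fluorophore
counts measure labeling efficiency.  `mtagmap` is for scientists who run or
model such experiments: it implements the full analysis chain and a
synthetic-data generator with ground truth, so every stage is testable.

The core pieces:

* **Reference maps** — motif site finding on both strands, in-silico PCR,
  FASTA in / BED out.
* **Simulation** — per-site Bernoulli labeling (probability `p_site`, at
  most one fluorophore per palindromic site, optional second-strand
  labels), homogeneous Poisson off-target labels (`rho_off` per kb),
  Gaussian localization error (`sigma_loc` bp), per-molecule stretch
  `s ~ N(1.6, (1.6·0.1)²)`, random orientation; plus two-channel plasmid
  fields, single-step photobleaching movies, and pseudo-first-order
  kinetics `N(t) = N∞(1 − e^(−k′t))`.
* **Bleaching-assisted localization** — backward pass through the movie:
  fit isolated 2D Gaussians in the terminal frames, estimate each
  emitter's bleach frame by a change point, subtract its PSF from earlier
  frames, repeat; then plasmid mask reconstruction (circularity filter
  `4πA/P² ≥ 0.6`) and per-plasmid label counting with
  `SEM = sd(X)/√N`.
* **Alignment** — a stretch-tolerant monotone dynamic program: matches
  within a 150 bp window score `1 − |Δ|/150`, skipped sites and extra
  labels pay penalties, stretch is searched over `1.6 ± 10%` with a global
  offset and polished by least squares; both orientations are tried.
* **Consensus & off-target statistics** — projection of aligned molecules
  onto reference coordinates, the dual-strand removal rule (one unaligned
  label within 100 bp of each aligned label), a 50 bp consensus histogram,
  and off-site fraction/density with window-truncation-corrected
  estimators.
* **Statistics** — kinetics fitting, the Poisson zero-class specificity
  bound `kb/(−ln f₀)`, fold changes, and site-count titration regression.

## Worked example

Simulate the combed-fragment regime — 180 molecules of a 5 kb amplicon
carrying 9 TCGA sites (with close pairs near 650 and 3000 bp), per-site
efficiency 0.92, 0.46 off-target labels/kb, 100 bp localization error,
stretch 1.6 ± 10%, random orientation — then align, build the consensus
and quantify off-target labeling:

```r
library(mtagmap)

cfg <- pipeline_config(n_molecules = 180, seed = 42)
cfg$consensus$apply_removal <- FALSE   # single-strand simulation
res <- run_pipeline(cfg)
res$offsite
#> offsite_stats: 1383 matched, 502 unmatched
#>   off-site fraction 26.6% (corrected 23.7%), density 0.558/kb (corrected 0.497/kb)
#>   per-site matched mean 0.854, efficiency 0.887 (capture 0.962, sigma 72.2 bp), uniformity p 0.003
res$consensus
#> consensus_histogram: 100 bins of 50 bp, 1885 labels from 180 molecules
```

Reading the numbers: of 1885 observed labels, 1383 matched a reference
site.  The raw unmatched fraction (26.6%) overstates off-target labeling
because a hard 150 bp match window lets some genuinely on-site labels
escape; the corrected estimators put the off-site fraction at 23.7% and
the density at 0.497/kb, close to the generator's truth regime (21.7%,
0.46/kb), and the per-site efficiency at 0.887 (truth 0.92).  The
uniformity p-value is small here because the unmatched class still
contains near-site escapees — with perfect matching it would be uniform.

Worked single-value examples:

```r
poisson_zero_bound(0.97, 2.6)   # >=97% of 2.6 kb plasmids label-free
#> [1] 85.36007                  #   -> one non-specific fluorophore per ~85 kb
fold_change(3.5, 1.3)           # one-pot vs two-step labeling means
#> [1] 2.692308                  #   -> the ~2.6-fold efficiency gain
```

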