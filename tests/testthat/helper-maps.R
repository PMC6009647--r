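## Shared fixtures: reference maps mirroring the study systems, built in code.

## 5 kb amplicon-like map with 9 palindromic sites, including the two close
## pairs (around 650 and 3000 bp) that should accumulate ~2x consensus counts
amp_sites <- c(600, 700, 1500, 2100, 2950, 3050, 3700, 4300, 4800)
amp_map <- reference_map("synthetic-amplicon", 5000, "TCGA", amp_sites)

## 2686 bp plasmid-like map with 4 sites
puc_sites <- c(400, 1000, 1900, 2500)
puc_map <- reference_map("synthetic-puc19", 2686, "TCGA", puc_sites)

## noiseless, unflipped simulation config
noiseless_cfg <- function(n = 1, seed = 1, p_site = 1)
  sim_config(p_site = p_site, rho_off = 0, sigma_loc = 0, stretch_tol = 0,
             flip_prob = 0, n_molecules = n, seed = seed)
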