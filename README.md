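# rodnet

Two-scale analysis of G-protein signalling in rod photoreceptors:

1. **Reaction-network modelling** of the phototransduction cascade —
   mass-action ODE integration of flash responses, dark-state
   rhodopsin–transducin precoupling, explicit grafting of a mutant
   Gα species with zygosity-dependent expression and fold-scaled
   kinetics, and photoresponse feature extraction (time to peak, peak
   amplitude, recovery time, half-maximal flash strength I₀).
2. **Structure-ensemble communication analysis** applicable to any
   conformational ensemble — protein structure networks (PSN) built
   from side-chain contacts, interaction-strength normalization with
   ligand nodes (GTP, Mg²⁺, water), largest-cluster-halving selection
   of the interaction cutoff I_min, hub detection, LMI-filtered
   deterministic shortest communication paths, meta-path recurrence,
   essential dynamics (PCA at 90 % variance), functional mode
   analysis (FMA), RMSD/RMSF and solvent-accessible surface area.

A synthetic-data module generates both toy cascades (with a
closed-form linear variant) and structure ensembles with *planted*
ground truth — low-rank correlated motions, persistent side-chain
contacts, ligand-like nodes — so that every analytic can be verified
against known answers without molecular-dynamics trajectories.

## Worked example: cascade

```r
library(rodnet)

net <- add_precoupling(gen_toy_cascade("cascade"))
dark_steady_state(net)$precoupled_fraction
#> [1] 0.2000001

resp <- simulate_flash(net, flash_stimulus(5), t_end = 40)
time_to_peak(resp)     #> [1] 1.84        (s)
peak_amplitude(resp)   #> [1] 0.5602760   (pA)
recovery_time(simulate_flash(net, flash_stimulus(5), t_end = 120))
#> [1] 10.57          (s, |dJ| stays within 1 % of dark thereafter)

fam  <- gen_flash_family(2, 5000, 7)
resp_fam <- lapply(fam, function(s) simulate_flash(net, s, t_end = 60))
half_max_intensity(normalize_family(resp_fam))
#> [1] 88.92618       (photons / um^2)
```

Graft a mutant Gα (heterozygous: 25 % mutant at native expression;
homozygous: all mutant at 35 % expression; activation rates kP1/kP2
cut 35 000-fold, GAP binding kRGS1 halved):

```r
het <- build_mutant(net, mutant_spec("heterozygous"))
hom <- build_mutant(net, mutant_spec("homozygous"))
peak_amplitude(simulate_flash(het, flash_stimulus(5), t_end = 40)) /
  peak_amplitude(resp)
#> [1] 0.7545438
peak_amplitude(simulate_flash(hom, flash_stimulus(5), t_end = 40)) /
  peak_amplitude(resp)
#> [1] 0.002177255
```

## Worked example: structure networks

```r
ens <- gen_ensemble(ensemble_spec(
  24, 400, sigma = 0.15, sidechain_atoms = 2,
  contacts = data.frame(i = c(1, 5, 9, 15), j = c(5, 9, 13, 20),
                        persistence = c(1, 0.9, 0.95, 0.85)),
  correlations = data.frame(i = 5, j = 13, rho = 0.7),
  ligands = "GTP", seed = 1))

g <- build_psg(ens)          # 30 % occurrence filter
nrow(g$edges)                #> [1] 4
optimal_imin(ens)            #> [1] 4.01

ps <- shortest_paths_psn(g, lmi_correlation(ens))
ps$path[1]                   #> [1] "A:1->A:5->A:9->A:13"

es <- pca_ensemble(ens)      # essential subspace at 90 % variance
fm <- fma(es, sasa_series(ens, nodes = "A:5")[, 1], n = 4)
```

Planted-truth recovery at scale (5 000 frames, 60 residues): mean
RMSF 0.4257 vs planted 0.4330 (σ√3), LMI 0.605 for a planted 0.6
correlation, FMA cross-validated r = 0.994 for an observable built
from the first two PCs, single-sphere SASA exact to the quadrature.

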