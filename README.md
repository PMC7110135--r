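# rad51kin

Mechanistic modelling of RAD51 polymerisation kinetics on DNA, as measured
by surface plasmon resonance (SPR).

## The problem

RAD51, the central recombinase of homologous recombination, polymerises on
single-stranded DNA to form the nucleoprotein filament that repairs
double-strand breaks — and it does so much faster on ssDNA than on dsDNA.
SPR experiments interrogate this discrimination directly: short
biotinylated oligonucleotides are immobilised on a chip, RAD51 flows over
them, and the chip reports bound mass (RU) through an association phase
and a buffer-only dissociation phase.

`rad51kin` is for quantitative biochemists analysing such data. It
implements:

* **Solution equilibrium.** RAD51 self-associates isodesmically — one
  dissociation constant `K_D` for every protomer–protomer interface. At
  steady state, detailed balance gives `[A_n] = [A_1]^n / K_D^(n-1)`, with
  the free monomer concentration solved from conservation
  `Σ n·[A_n] = total`. A brute-force mass-action ODE integration of the
  full network (every association `n + m -> (n+m)`, every split) serves as
  an independent oracle for this closed form.
* **Filament kinetics.** On a substrate accommodating `c` protomers (one
  per 3 nt; 16 on a 50-mer), filament formation is a linear Markov chain
  over states `0..c`: any solution n-mer adsorbs or elongates at rate
  `k_p·[A_n]`; dissociation runs through substrate-specific reverse-rate
  classes (`k_u` for unstable 1–3-mer nuclei, `k_q` for the quasi-stable
  4-mer on ssDNA, `k_s` for stable filaments; a single `k_pr` for the
  self-association-weakened F86E mutant). Propagation is by matrix
  exponentials, cross-checked against a stiff integrator.
* **Sensorgram processing.** Double-referencing (control cell and drift
  subtraction) and the mass-ratio normalization
  `N = S / (L · M_RAD51 / M_DNA)`, converting RU to mean RAD51 per DNA.
* **Synthetic studies.** Presets reproducing the 8-curve wild-type design
  (dN-8/14/17/50 ssDNA + dN-5p/8p/11p/50p dsDNA) and the 4-curve F86E
  flexibility series (dT-50, dN-50, dA-50, dN-50p), with additive RU noise
  and drift — so the whole pipeline is testable without instrument data.
* **Inference.** ABC-SMC (log-uniform priors, adaptive tolerance
  schedule, multivariate Gaussian kernel in log space, mode-particle
  reporting) for the joint fits with a shared `K_D`, plus bounded
  least-squares refits of single rate constants, replicate aggregation and
  exact Mann–Whitney–Wilcoxon comparisons.

## A worked example

Simulate a wild-type dN-50 injection at 150 nM, normalize it and refit the
forward rate:

```r
library(rad51kin)

sub   <- get_substrate("dN-50")          # 50-nt ssDNA, 15.682 kDa, capacity 16
truth <- wt_parameter_preset()           # K_D = 1.14 nM, ss k_p = 2.6e-2 /uM/s
proto <- injection_protocol(0.15, t_association_s = 60,
                            t_dissociation_s = 1200)

curve <- simulate_curve(sub, truth$ss, proto)
max(curve$n_bound)
#> [1] 0.2231287

dist <- polymer_distribution(truth$kd_um, 0.15)
round(percent_in_state(dist)[c(1, 8, 16)], 3)
#> [1]  0.758  5.935 11.588

start <- truth$ss; start$kp <- 1e-3
lsq_refit(curve, sub, start, free = "kp", protocol = proto)$par
#>    kp
#> 0.026
```

At 150 nM free RAD51 the nanomolar `K_D` puts most protein in long
polymers (the 16-mer state alone carries ~12 % of all monomers), which is
what lets RAD51 coat 50-mers quickly even at low concentration; the refit
recovers the generating forward rate `k_p = 2.6e-2 /uM/s` exactly, and the
ssDNA/dsDNA refit ratio reproduces the characteristic 6.5-fold
polymerisation advantage on flexible ssDNA.

The full study pipelines — generate (or load), fit per replicate,
aggregate mode particles, compare rates — are one call each:

```r
report <- run_wt_study(n_replicates = 3, noise_sd_ru = 0.3, seed = 1)
report$summary         # posterior-mode parameters, mean +- SD over replicates
```

## Documentation

The methods vignette (`vignettes/rad51-kinetics.Rmd`) describes the model
assumptions, parameters and units, the synthetic-data generator, the
ABC-SMC design choices and known limitations.
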