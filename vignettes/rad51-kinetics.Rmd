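---
title: "Modelling RAD51 polymerisation on DNA from SPR sensorgrams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling RAD51 polymerisation on DNA from SPR sensorgrams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rad51kin)
```

## The scientific problem

RAD51 is the central recombinase of homologous recombination: it
polymerises on resected single-stranded DNA (ssDNA) to form the
nucleoprotein filament that drives strand invasion. Biochemically it
polymerises much faster on ssDNA than on double-stranded DNA (dsDNA), and
the kinetic basis of that discrimination can be interrogated by surface
plasmon resonance (SPR): short biotinylated oligonucleotides are
immobilised on a chip, RAD51 is flowed over them (association), then buffer
alone (dissociation), and the chip reports bound mass in resonance units
(RU) over time.

`rad51kin` implements the full quantitative pipeline for such experiments:

1. a steady-state model of RAD51 self-association in solution,
2. linear kinetic models of filament formation on a DNA substrate,
3. sensorgram referencing and normalization,
4. a synthetic sensorgram generator,
5. ABC-SMC inference of the kinetic parameters and least-squares refits.

## Substrates and capacity

One RAD51 protomer engages three nucleotides, so a substrate of `L`
nucleotides (base pairs for duplexes) carries at most `floor(L / 3)`
protomers: a 17-mer carries five, a 50-mer sixteen. The packaged catalogue
(`substrate_catalog()`) lists the twelve oligonucleotides of the study
design with their molar masses; the four 50-mers additionally carry
SAXS-derived Kuhn lengths, converted to persistence lengths as
`L_p = Kuhn / 2`. Duplexes are treated as single species whose catalogue
mass covers both strands and linkers — SPR weighs the whole immobilised
molecule, which is what the normalization needs.

```{r}
get_substrate("dN-50")
```

## RAD51 polymers in solution

In solution, any RAD51 n-mer can bind any m-mer, and any k-mer can fall
apart at any interface. With one dissociation constant $K_D$ for every
protomer–protomer interface (isodesmic assembly), detailed balance across
every association channel forces the steady state

$$[A_n] = \frac{[A_1]^n}{K_D^{\,n-1}}, \qquad n = 1, \dots, N_{max},$$

with $[A_1]$ fixed by monomer conservation $\sum_n n [A_n] = A_{tot}$.
`polymer_distribution()` solves the conservation equation by bracketed root
finding on $(0, A_{tot}]$ (the left side is strictly increasing in
$[A_1]$, so the bracket is guaranteed), followed by a few Newton polish
steps. $N_{max} = 16$ by default — the capacity of a 50-mer.

Because the closed form is an equilibrium argument, not an integration,
`steady_state_oracle()` provides an independent check: it integrates the
full mass-action network (120 association channels at $N_{max} = 16$, each
with its reverse split) to steady state with a stiff integrator. The two
agree to better than $10^{-6}$ relative error across the grid of
$(K_D, A_{tot})$ exercised in the tests. A `symmetry` toggle applies the
statistical factor 1/2 to identical-reactant channels in the oracle; the
factor cancels at detailed balance, so the equilibrium — and hence
everything downstream — is unchanged by the convention.

Two caveats documented as properties: truncating the ladder at
$N_{max}$ *overestimates* each tracked species (mass that would sit in
longer polymers is redistributed), and the fraction of RAD51 in long
polymers rises with total concentration and falls with $K_D$.

```{r}
head(as.data.frame(polymer_distribution(1.14e-3, 0.15)), 4)
```

## Filament kinetics on DNA

During an injection, flow holds the solution distribution constant, so
filament formation on a substrate of capacity $c$ is a linear Markov chain
on states $0..c$ — the length of the single polymer carried by a DNA
molecule ($j = 0$ is bare DNA; multi-nucleation on one molecule is
excluded, consistent with the short substrates used). For a 50-mer this
gives the 17-state system (16 bound states plus bare DNA).

* **Forward:** any solution n-mer adsorbs onto bare DNA, and any m-mer
  elongates a bound polymer, at one aggregate rate $k_p [A_m]$ per channel
  (no size dependence; capture at either filament end is absorbed into
  $k_p$).
* **Reverse (wild type, ssDNA):** unstable nuclei of 1–3 protomers shrink
  at $k_u$, the quasi-stable 4-mer nucleus at $k_q$, and stable polymers
  ($j \ge 5$) lose single protomers at $k_s$.
* **Reverse (wild type, dsDNA):** lone monomers leave at $k_u$; polymers
  of two or more lose protomers at $k_s$ (nucleation on dsDNA needs only
  two molecules, so no separate quasi-stable class).
* **Reverse (F86E):** one rate $k_{pr}$ for every state — the
  self-association-weakened mutant data cannot resolve separate classes.

The default reverse topology is *stepwise* ($j \to j-1$); a
*whole-nucleus* alternative ($j \le 3 \to 0$ at $k_u$, $4 \to 0$ at
$k_q$) is available via `reverse_topology = "whole_nucleus"`, since the
available evidence does not decide between them — unstable nuclei could
plausibly detach whole. Both satisfy every structural invariant
(probability conservation, monotone dissociation), and $k_u$ is in any
case weakly determined by data of this design, so the choice is weakly
constrained; stepwise keeps the chain strictly tridiagonal in its reverse
part and is the default.

Propagation uses matrix exponentials (scaling-and-squaring with a
doubling scheme over the uniform sampling grid), with an adaptive stiff
integrator (`deSolve::lsoda`, rtol $10^{-10}$, atol $10^{-12}$) as a
cross-checking backend; the two agree to $10^{-8}$ in the tests. The
mean occupancy $N(t) = \sum_j j D_j(t)$ is the model-side analogue of a
normalized sensorgram. The dissociation phase re-builds the rate matrix
with all solution concentrations zero: buffer flow removes free RAD51
instantly and there is no rebinding from bulk.

## Sensorgram processing

Referencing follows standard double-referencing: subtract the control
flow-cell trace, subtract the residual drift trace recorded during the
final buffer priming, zero the 5 s pre-injection window. Injection start
comes from metadata, never from signal detection. Normalization converts
RU to mean RAD51 per DNA molecule:

$$N = \frac{S}{L \cdot (M_{RAD51} / M_{DNA})},$$

with $M_{RAD51} \approx 37$ kDa and the catalogue mass for the substrate;
$L$ is the immobilised DNA level in RU. The familiar 1 RU ≈ 50 pg/mm²
conversion is recorded for reference but never used — the normalization
needs only RU ratios. Sensorgrams travel as plain CSV
(`time_s,response_ru`) with YAML metadata in `#`-prefixed header lines;
vendor export formats vary too much to guess, so the package defines one
minimal dialect and a permissive reader.

## The synthetic study designs

`wt_design_preset()` reproduces the eight-curve wild-type experiment:
dN-8, dN-14, dN-17, dN-5p, dN-8p and dN-11p at 3 µM and the two 50-mers at
0.15 µM (20-fold lower), 60 s association, 1200 s (20 min) dissociation,
sampled at 1 Hz / 0.5 Hz. `f86e_design_preset()` reproduces the
four-curve F86E flexibility series (dT-50, dN-50, dA-50, dN-50p, all at
30 µM). The 60 s association is the one protocol parameter not uniformly
reported per experiment; the value used for the composition snapshots is
adopted as the default throughout.

The generator simulates each curve through the kinetic model, converts
$N(t)$ back to RU through the inverse normalization (ligand level
default 12 RU, inside the reported 8–15 RU immobilisation window), and
adds i.i.d. Gaussian RU noise (default sd 0.3 RU, a realistic Biacore
noise floor) plus optional linear baseline drift. Noise is additive on
RU — where the instrument adds it — not on $N$.

The generating parameter sets (`wt_parameter_preset()`,
`f86e_parameter_preset()`) use the jointly fitted values where those are
printed: $K_D = 1.14$ nM (wild type), $K_D = 10.2$ µM (F86E), ssDNA
$k_p = 2.6\times10^{-2}$ and dsDNA $k_p = 4\times10^{-3}$ /µM/s, and the
dsDNA stable reverse rate below its reported $10^{-3}$/s upper bound. The
remaining rates are not printed numerically anywhere recoverable; the
presets fix them once at field-realistic scales consistent with the
qualitative findings: unstable nuclei too short-lived to accumulate
($k_u = 0.1$/s), a quasi-stable class two orders slower
($k_q = 10^{-2}$/s), near-irreversible protomer loss from stable
filaments ($k_s = 10^{-4}$/s, lifetime of hours), and F86E forward/reverse
pairs ordered by DNA flexibility with the dN-50p reverse rate below its
$10^{-3}$/s bound. These are stand-ins for bar-plot values, chosen before
any fitting and not revisited; recovery benchmarks score the *recovery* of
whatever the generator used, so their exact values matter less than their
scales.

What the generator does *not* emulate: bulk refractive-index spikes,
regeneration scars, mass-transport limitation, baseline steps between
cycles. Passing recovery benchmarks therefore demonstrates that the
inference machinery is correct and well-conditioned under the study
design — not that real Biacore artefacts are handled.

## ABC-SMC inference

The likelihood is intractable only in the trivial sense (deterministic
model, arbitrary distance), but the study follows the likelihood-free
route to match the original analysis. `abc_smc_fit()` implements the
sequential Monte Carlo scheme with importance-weighted particles:

* **Parameter space.** Everything runs in $\log_{10}$ units, matching the
  log-uniform priors. The wild-type joint fit has 8 parameters (shared
  $K_D$; four ssDNA rates; three dsDNA rates), the F86E fit 9 (shared
  $K_D$; per-curve $k_p, k_{pr}$). Prior bounds are taken as printed, in
  µM and /s — the concentration unit is not stated with the bounds, but
  µM makes both the wild-type window ($10^{-4}$–$10^{-1}$, containing
  1.14 nM = $1.14\times10^{-3}$ µM) and the F86E window (containing
  10.2 µM) sensible, which nM or M would not.
* **Distance.** Sum over curves of the mean squared deviation of $N(t)$,
  each curve weighted by $1/\max(1, c^2)$ (capacity-based) by default, so
  a 16-mer-capacity curve cannot drown out a 1-protomer curve by amplitude
  alone. An amplitude-balanced alternative (`amplitude_weights()`, every
  term a relative error) is available for designs whose occupancies sit
  far below capacity.
* **Tolerance schedule.** Generation 1 samples the prior; by default
  every draw is kept ($\varepsilon_1 = \infty$), and with
  `n_prior_draws` above the particle count the best draws are kept
  instead, making $\varepsilon_1$ finite. Afterwards $\varepsilon_t$ is
  the `quantile`-quantile of the previous generation's accepted distances
  (floored so at least 16 source particles remain). The function default
  is the conventional median, but the study pipeline and benchmarks run
  `quantile = 0.1`: near the optimum the distance is locally quadratic in
  $k$ effective parameters, so accepted distances pile up just below
  $\varepsilon$ and the median schedule contracts by only
  $q^{2/k} \approx 0.8$ per generation — far too slow for a
  six-generation run. $q = 0.1$ trades roughly five-fold more simulations
  per generation for contraction the short budget actually needs.
* **Perturbation kernel and resampling.** Each generation resamples (by
  importance weight) only the previous particles that already satisfy the
  new tolerance — partial rejection control; since the tolerance is a
  quantile of their distances this set is never empty, and the importance
  correction uses the same survivor mixture, so it stays exact. Proposals
  are perturbed with a multivariate Gaussian in $\log_{10}$ space whose
  covariance is twice the weighted sample covariance of the survivor set.
  The full covariance matters: $K_D$ and the forward rates are strongly
  correlated a posteriori, and a componentwise kernel proposes mostly
  off-ridge. Importance weights use the standard correction — uniform
  prior density over the kernel mixture evaluated at the proposal.
* **Mode reporting.** `posterior_mode()` estimates each marginal by a
  weighted Gaussian kernel density in $\log_{10}$ space (Silverman
  bandwidth on the effective sample size) and reports the
  highest-density *particle coordinate* (ties break toward the lower
  value) — the mode-particle convention, which never reports a smoothed
  interpolate that no particle attained.
* **Replicates.** `run_wt_study()` / `run_f86e_study()` fit each
  replicate separately and aggregate the per-replicate mode particles as
  mean ± SD, mirroring the three-repeat design; fitted rates across
  conditions are compared with the exact Mann–Whitney–Wilcoxon test
  (`compare_rates()`, mid-ranks under ties).

Degenerate inputs are handled explicitly: an acceptance rate collapsing
below a configurable floor aborts with diagnostics rather than spinning;
an empty population refuses to produce a mode; a curve set missing a
design substrate is reported by name.

### What is and is not identifiable

On noise-free synthetic data of the wild-type design, the shared $K_D$
and both forward rates concentrate strongly; the unstable reverse rates
$k_u$ stay essentially prior-like — the substrates that would determine
them (dN-8, dN-5p) barely accumulate RAD51, and monomer/dimer/trimer
concentrations in solution are low at the injection concentrations. A
dsDNA $k_s$ generated at 0 returns only an upper bound. Both behaviours
reproduce the identifiability pattern of the original analysis and are
asserted in the tests.

The F86E design is harder. All four curves share one concentration
(30 µM), so $K_D$ enters only through the solution composition, and
almost any $K_D$ admits per-curve rate pairs that fit the curves closely:
profiling the distance over fixed $K_D$ (rates re-optimised) gives
$\sim 3\times10^{-6}$ at $K_D$ off by a factor of five and
$\sim 5\times10^{-5}$ even at $K_D$ off by 200-fold, while six
256-particle generations reach $\varepsilon \approx 3\times10^{-3}$.
Resolving $K_D$ therefore needs tolerances two to three orders below
what the reduced preset can reach; at that preset the $K_D$ marginal
stays broad and its mode is unstable across seeds, and only a longer run
(more generations, larger populations) pins it. The per-curve forward
rates, by contrast, recover to within tens of percent. This is a
documented limitation of the reduced benchmark, not of the experimental
information as such.

## Least-squares refits

`lsq_refit()` performs the complementary frequentist check: hold all
parameters at the joint-fit means, free one (or two) rate constants, and
fit a single curve by bounded Levenberg–Marquardt in $\log_{10}$ space.
Self-consistency on synthetic curves recovers the generating rate to
six decimal places, and refitting the two 50-mers reproduces the
6.5-fold ssDNA/dsDNA forward-rate ratio
($2.6\times10^{-2} / 4\times10^{-3}$).

## Problem sizes and determinism

The recovery benchmarks in the tests and the acceptance script run the
reduced preset — 256 particles × 6 generations, noise-free data — which
completes in minutes on one core while leaving the identifiable
parameters well resolved; the package defaults (512 × 8) are preferred
for real analyses. Every stochastic step (noise generation, prior
sampling, resampling, perturbation) flows from a single integer seed, and
a fixed seed reproduces particle populations bit for bit.

## Known limitations

* The solution ladder stops at 16-mers; at high RAD51 concentration real
  polymers grow longer, so each tracked species is overestimated.
* One polymer per DNA molecule: appropriate for ≤ 50-mers, wrong for long
  substrates where multi-nucleation dominates.
* No ATP-hydrolysis-coupled disassembly — the experimental condition
  (Ca²⁺/ATP) blocks hydrolysis, and the model inherits that restriction.
* The normalization treats the mass-to-RU response as common to protein
  and DNA; refractive-index differences between them are ignored.
* Association duration defaults to 60 s everywhere; experiments with
  other durations must say so in their protocol metadata.
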