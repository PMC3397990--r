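# grndesign

Calibrating gene-regulatory-network (GRN) ODE models is mostly a data
problem: with only wildtype time courses, many kinetic parameters are
practically non-identifiable, and buying the *right* perturbation
experiment matters more than any amount of optimizer tuning. `grndesign`
implements the full loop for that situation, aimed at systems biologists
benchmarking calibration strategies on simulated GRNs:

* **Simulation** — Hill-kinetics transcription plus mass-action
  translation, `d mRNA_g/dt = pro_g · Σ hill(p; h, Kd) − δm·mRNA_g`,
  `d p_g/dt = rbs_g·mRNA_g − δp·p_g`, with knockout, siRNA (5× mRNA
  degradation) and rbs-doubling perturbations; adaptive stiff
  (Rosenbrock) and Dormand–Prince integrators with forward sensitivity
  equations, implemented in C++.
* **Estimation** — maximum likelihood in log10 parameter space under an
  absolute + relative Gaussian error model with zero-clipping
  (`σ²(x) = σ_abs² + (σ_rel·x)²`), latin-hypercube multi-starts, a
  trust-region optimizer fed analytic sensitivity gradients and a
  Gauss–Newton Hessian, and a χ² threshold for discriminating competing
  local optima.
* **Identifiability** — profile likelihoods with adaptive stepping,
  likelihood-ratio confidence intervals
  (`PL ≥ LL* − χ²_{0.95}(1)/2`), and classification into identifiable /
  practically / structurally non-identifiable.
* **Experimental design** — every purchasable experiment (perturbation ×
  readout, plus gel-shifts that measure an interaction's `h` and `Kd`
  exactly) is scored by the noise-normalized spread
  `R(D) = max_{i,t} [max_θ x_i(t;θ) − min_θ x_i(t;θ)] / σ_i(t)` of
  predictions across profile-derived parameter vectors; ranking breaks
  near-ties (within 10 %) by cost.
* **Virtual laboratory** — hidden truth parameters, noisy data vending, a
  credit ledger (two-protein time course 400 credits, high-density
  microarray 1000, gel-shift 1600, siRNA surcharge 350, …, budget
  10 000), and an automated benchmark loop comparing purchasing
  strategies.

## Worked example

```r
library(grndesign)
set.seed(1)

s <- synth_network(6, 8, seed = 42)   # random 6-gene wiring + hidden truth
net <- s$network
count_parameters(net)
#> [1] 29
nrow(enumerate_designs(net))
#> [1] 331

# a virtual lab hides the truth behind 10k credits and vends free
# wildtype mRNA data; buy one wildtype protein pair on top
lab <- challenge_init(net, s$theta_true, seed = 42)
lab <- purchase(lab, "wt:protein_pair_p1_p2")
lab
#> challenge_state: 6 genes; 9600 of 10000 credits remaining; 140 data
#>   points; 2 purchases; 0 directly measured parameters

# fit, profile, and ask what to buy next
obj <- make_objective(net, lab$data, lab$conditions)
ms  <- multistart_fit(obj, n_starts = 20, seed = 1)
ens <- profile_ensemble(obj, ms$best,
                        control = profile_control(max_steps = 6))
count_non_identifiable(ens)
#> [1] 21

stilde <- profile_parameter_set(ens, max_per_profile = 3)
cls    <- sapply(ens$profiles, classify_identifiability)
scores <- score_designs(net, stilde, enumerate_designs(net),
                        theta_hat = ms$best$par,
                        nonid_params = names(cls)[cls != "identifiable"])
head(rank_designs(scores, budget = lab$budget)$recommended[
  c("id", "R", "cost")], 3)
#>             id   R cost
#> 1 gelshift_1_2 Inf 1600
#> 2 gelshift_1_3 Inf 1600
#> 3 gelshift_1_4 Inf 1600
```

With a single wildtype protein pair on top of the free mRNA data, 21 of
the 29 parameters are still non-identifiable; the ranking puts gel-shift
measurements of unresolved interactions first (they pin two parameters
outright), with the most informative perturbation time courses next.
Buying the recommendation, refitting and re-profiling closes confidence
intervals step by step — `run_benchmark_loop()` automates exactly that
and shows the profile-guided strategy beating random purchasing on the
distance to the hidden truth.

(Numbers above are what the code prints under these seeds; fits and
profiles here use small multistart/profile settings for brevity.)

## Acceptance script

`scripts/acceptance.R` rebuilds networks of the three benchmark sizes
with the package's own generator and recomputes, from scratch, the free
kinetic parameter counts for the (6-gene, 8-interaction), (7, 10) and
(9, 15) models and the size of the purchasable design space for the
9-gene model:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Command line

A thin CLI over the same functions lives in `inst/cli/grnlab.R`
(`fit`, `profile`, `design` subcommands on JSON/CSV files); the R
functions and the methods vignette (`vignettes/methods.Rmd`) are the
primary interface.
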