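# Shared fixtures: small networks, simulated datasets and toy objectives,
# all generated in code under fixed seeds.

single_gene <- function() gene_network("1")

single_gene_truth <- function() log10(c(pro_1 = 2, rbs_1 = 1, delta_p = 0.5))

# dataset of both species of the single-gene model on a given grid
single_gene_data <- function(truth = single_gene_truth(),
                             times = readout_times("protein_pair"),
                             noise = noise_model(), noisy = TRUE,
                             net = single_gene()) {
  tr <- simulate_grn(net, truth, times)
  x <- pmax(as.vector(tr$states), 0)
  y <- if (noisy) simulate_measurement(x, noise) else x
  grn_dataset("wt", rep(rownames(tr$states), length(times)),
              rep(times, each = nrow(tr$states)), y)
}

# wildtype data for all species of an arbitrary network
wt_data <- function(net, truth, times = readout_times("ma_high"),
                    noise = noise_model(), noisy = TRUE,
                    species = NULL) {
  tr <- simulate_grn(net, truth, times)
  st <- if (is.null(species)) tr$states else tr$states[species, , drop = FALSE]
  x <- pmax(as.vector(st), 0)
  y <- if (noisy) simulate_measurement(x, noise) else x
  grn_dataset("wt", rep(rownames(st), length(times)),
              rep(times, each = nrow(st)), y)
}

# independent-quadratic toy likelihood: NLL = sum((theta - a)^2 / (2 s^2));
# profile CIs are exactly a_i +/- z * s_i
quadratic_objective <- function(a, s, box = 5) {
  stopifnot(length(a) == length(s))
  nm <- names(a)
  objective_function(
    fn = function(theta) sum((theta - a)^2 / (2 * s^2)),
    gr = function(theta) (theta - a) / s^2,
    lower = setNames(a - box, nm), upper = setNames(a + box, nm))
}

# correlated-Gaussian toy: NLL = 0.5 (theta-a)' H (theta-a); profile CI of
# component i is a_i +/- z * sqrt((H^-1)_ii)
gaussian_objective <- function(a, H, box = 5) {
  nm <- names(a)
  objective_function(
    fn = function(theta) 0.5 * drop(t(theta - a) %*% H %*% (theta - a)),
    gr = function(theta) drop(H %*% (theta - a)),
    lower = setNames(a - box, nm), upper = setNames(a + box, nm))
}

fast_profile <- function(...) {
  profile_control(..., reopt_control = list(iter.max = 60, eval.max = 120))
}
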