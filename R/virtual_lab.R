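#' Cost table for purchasable experiments
#'
#' Default credits follow the challenge arithmetic: a two-protein time
#' course costs 400 (80 data points, 0.2 points/credit), a high-density
#' microarray 1000, a gel-shift (one interaction, both parameters) 1600,
#' and perturbed time courses add a surcharge on top of the readout price
#' (siRNA 350, so the cheapest perturbation data set costs 750; rbs
#' doubling 450). The low-density microarray price (600) and the knockout
#' surcharge (550) are package defaults with no challenge counterpart —
#' configurable here.
#'
#' @param protein_pair,ma_high,ma_low,gelshift readout prices in credits.
#' @param sirna,rbs_boost,knockout perturbation surcharges.
#' @param initial_budget starting credits.
#' @return object of class `cost_table`.
#' @export
cost_table <- function(protein_pair = 400, ma_high = 1000, ma_low = 600,
                       gelshift = 1600, sirna = 350, rbs_boost = 450,
                       knockout = 550, initial_budget = 10000) {
  ct <- list(readout = c(protein_pair = protein_pair, ma_high = ma_high,
                         ma_low = ma_low, gelshift = gelshift),
             surcharge = c(sirna = sirna, rbs_boost = rbs_boost,
                           knockout = knockout),
             initial_budget = initial_budget)
  if (any(unlist(ct) <= 0)) stop("all costs must be positive")
  structure(ct, class = "cost_table")
}

#' @rdname cost_table
#' @param path JSON file path.
#' @export
read_cost_table <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(cost_table, as.list(c(x$readout, x$surcharge,
                                initial_budget = x$initial_budget)))
}

#' @rdname cost_table
#' @param costs a `cost_table`.
#' @export
write_cost_table <- function(costs, path) {
  jsonlite::write_json(unclass(costs), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Built-in stand-in network topologies
#'
#' Three fixed wirings with the challenge models' sizes — (6 genes,
#' 8 interactions), (7, 10) and (9, 15), hence 29, 35 and 49 free kinetic
#' parameters. These are stand-ins of the package's own design, not the
#' challenge topologies.
#'
#' @param name `"model_a"`, `"model_b"` or `"model_c"`.
#' @return a [gene_network()].
#' @export
example_network <- function(name = c("model_a", "model_b", "model_c")) {
  name <- match.arg(name)
  edges <- switch(name,
    model_a = list(genes = 6, e = rbind(
      c(1, 2, "a"), c(2, 3, "r"), c(3, 4, "a"), c(4, 5, "r"),
      c(5, 6, "a"), c(6, 1, "r"), c(1, 4, "a"), c(3, 6, "r"))),
    model_b = list(genes = 7, e = rbind(
      c(1, 2, "a"), c(2, 3, "r"), c(3, 4, "a"), c(4, 5, "r"),
      c(5, 6, "a"), c(6, 7, "r"), c(7, 1, "a"), c(2, 5, "r"),
      c(4, 1, "a"), c(6, 3, "r"))),
    model_c = list(genes = 9, e = rbind(
      c(1, 2, "a"), c(2, 3, "r"), c(3, 4, "a"), c(4, 5, "r"),
      c(5, 6, "a"), c(6, 7, "r"), c(7, 8, "a"), c(8, 9, "r"),
      c(9, 1, "a"), c(1, 5, "a"), c(3, 7, "r"), c(5, 9, "a"),
      c(7, 2, "r"), c(9, 4, "a"), c(2, 6, "r"))))
  gene_network(as.character(seq_len(edges$genes)),
               data.frame(from = edges$e[, 1], to = edges$e[, 2],
                          sign = ifelse(edges$e[, 3] == "a", "activation",
                                        "repression"),
                          stringsAsFactors = FALSE))
}

#' Generate a random network and hidden truth parameters
#'
#' Topology: a random weakly connected wiring (when `I >= G - 1`; a
#' spanning arborescence rooted at gene 1 is laid first, then extra edges),
#' no self-loops, no duplicate edges, signs uniform. Gene 1 receives no
#' regulators whenever the edge budget allows it (`I <= (G - 1)^2`), so the
#' network always contains a constitutively transcribed source gene:
#' with zero basal transcription an activation-only circuit without such a
#' root never turns on and generates identically dark, uninformative data.
#' Truth parameters: non-Hill parameters
#' log-uniform over the default search box (log10 in `[-2, 3]`); Hill
#' coefficients uniform on the integers 1..8, so boundary values occur with
#' positive probability (a known source of apparent non-identifiability
#' when the search box for Hill coefficients is `[1, 8]`).
#'
#' @param G number of genes (>= 1).
#' @param I number of interactions (`<= G * (G - 1)`).
#' @param seed RNG seed (reproducible network + truth).
#' @return list with `network` and `theta_true` (named, log10 scale).
#' @export
synth_network <- function(G, I, seed = NULL) {
  stopifnot(G >= 1, I >= 0)
  if (I > G * (G - 1)) stop("I exceeds G*(G-1): no room for ", I,
                            " distinct directed interactions")
  if (!is.null(seed)) set.seed(seed)
  genes <- as.character(seq_len(G))
  from <- integer(0); to <- integer(0)
  if (I >= G - 1 && G > 1) {
    to <- 2:G
    from <- vapply(2:G, function(g) sample.int(g - 1, 1), integer(1))
  }
  all_pairs <- expand.grid(from = seq_len(G), to = seq_len(G))
  all_pairs <- all_pairs[all_pairs$from != all_pairs$to, ]
  if (I <= (G - 1)^2)  # keep gene 1 constitutive when there is room
    all_pairs <- all_pairs[all_pairs$to != 1L, ]
  have <- paste(from, to)
  pool <- all_pairs[!paste(all_pairs$from, all_pairs$to) %in% have, ,
                    drop = FALSE]
  extra <- I - length(from)
  if (extra > 0) {
    pick <- pool[sample.int(nrow(pool), extra), ]
    from <- c(from, pick$from); to <- c(to, pick$to)
  }
  ia <- if (I > 0) data.frame(
    from = genes[from], to = genes[to],
    sign = sample(c("activation", "repression"), I, replace = TRUE),
    stringsAsFactors = FALSE) else NULL
  net <- gene_network(genes, ia)
  info <- param_info(net)
  theta <- ifelse(info$type == "hill",
                  log10(sample(1:8, nrow(info), replace = TRUE)),
                  runif(nrow(info), -2, 3))
  list(network = net, theta_true = setNames(theta, info$name))
}

#' Initialize a virtual challenge
#'
#' Sets up the simulated laboratory: a network with hidden truth
#' parameters, a credit budget, and a start-up dataset of wildtype mRNA
#' measurements (low-density grid — the free glimpse every participant
#' receives). All vended data derive deterministically from `seed` and the
#' purchase ledger.
#'
#' @param network a [gene_network()].
#' @param theta_true hidden truth, named log10 vector.
#' @param seed integer seed controlling every noise realization.
#' @param costs a [cost_table()].
#' @param noise a [noise_model()].
#' @param horizon measurement horizon (time units).
#' @param initial_data `"ma_low"` (default), `"ma_high"` or `"none"`.
#' @return object of class `challenge_state`.
#' @export
challenge_init <- function(network, theta_true, seed = 1,
                           costs = cost_table(), noise = noise_model(),
                           horizon = 20, initial_data = "ma_low") {
  theta_true <- theta_true[param_info(network)$name]
  if (anyNA(theta_true)) stop("theta_true must name every parameter")
  state <- structure(list(
    network = network, theta_true = theta_true, seed = as.integer(seed),
    costs = costs, noise = noise, horizon = horizon,
    budget = costs$initial_budget,
    ledger = data.frame(purchase = integer(), id = character(),
                        cost = numeric(), remaining = numeric(),
                        stringsAsFactors = FALSE),
    data = grn_dataset(character(), character(), numeric(), numeric()),
    conditions = list(),
    known_params = numeric(0),
    n_purchases = 0L), class = "challenge_state")
  if (initial_data != "none") {
    grid <- readout_times(initial_data, horizon)
    state <- vend_timecourse(state, "wt", perturbation("wildtype"),
                             paste0("mRNA", network$genes), grid)
  }
  state
}

#' @export
print.challenge_state <- function(x, ...) {
  cat("challenge_state:", length(x$network$genes), "genes;",
      x$budget, "of", x$costs$initial_budget, "credits remaining;",
      nrow(x$data), "data points;", x$n_purchases, "purchases;",
      length(x$known_params), "directly measured parameters\n")
  invisible(x)
}

# internal: deterministic per-purchase RNG stream
vend_seed <- function(state, k) {
  as.integer((abs(state$seed) %% 1000003L) * 1009L + k) %% 2147483647L
}

# internal: simulate truth under a perturbation and vend noisy records
vend_timecourse <- function(state, cond_id, pert, species, times) {
  tr <- simulate_grn(state$network, state$theta_true, times, pert = pert,
                     rtol = 1e-8, atol = 1e-10)
  x <- as.vector(tr$states[species, , drop = FALSE])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  set.seed(vend_seed(state, state$n_purchases))
  y <- simulate_measurement(pmax(x, 0), state$noise)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  new <- grn_dataset(cond_id, rep(species, times = length(times)),
                     rep(times, each = length(species)), y)
  state$data <- rbind(state$data, new)
  if (!cond_id %in% names(state$conditions))
    state$conditions[[cond_id]] <- pert
  state$n_purchases <- state$n_purchases + 1L
  state
}

#' Purchase an experiment
#'
#' Deducts the design's cost from the budget and vends the result:
#' time-course designs return fresh noisy measurements of the hidden truth
#' under the design's perturbation (appended to `state$data`); gel-shift
#' designs return the interaction's Hill coefficient and Kd exactly
#' (appended to `state$known_params`, log10 scale). An unaffordable
#' purchase is refused with an error of class `grn_insufficient_credits`
#' carrying the shortfall.
#'
#' @param state a `challenge_state`.
#' @param design one row of [enumerate_designs()], or a design `id` string.
#' @return the updated state (ledger appended; data or known parameters
#'   extended).
#' @export
purchase <- function(state, design) {
  if (is.character(design)) {
    all <- enumerate_designs(state$network, state$costs)
    design <- all[all$id == design, , drop = FALSE]
    if (!nrow(design)) stop("unknown design id")
  }
  design <- design[1, , drop = FALSE]
  if (design$cost > state$budget) {
    shortfall <- design$cost - state$budget
    stop(structure(class = c("grn_insufficient_credits", "error",
                             "condition"),
                   list(message = paste0("insufficient credits: need ",
                                         design$cost, ", have ",
                                         state$budget, " (shortfall ",
                                         shortfall, ")"),
                        call = NULL, shortfall = shortfall)))
  }
  if (design$readout_type == "gelshift") {
    ia <- state$network$interactions[design$interaction, ]
    pn <- paste0(c("h_", "Kd_"), ia$from, "_", ia$to)
    state$known_params[pn] <- state$theta_true[pn]
    state$n_purchases <- state$n_purchases + 1L
  } else {
    state <- vend_timecourse(
      state, design_condition_id(design), design_perturbation(design),
      design_species(design, state$network),
      readout_times(design$readout_type, state$horizon))
  }
  state$budget <- state$budget - design$cost
  state$ledger <- rbind(state$ledger, data.frame(
    purchase = state$n_purchases, id = design$id, cost = design$cost,
    remaining = state$budget, stringsAsFactors = FALSE))
  state
}

#' Data points obtained per credit spent
#'
#' @param purchase_type `"protein_pair"`, `"ma_high"`, `"ma_low"` or
#'   `"gelshift"`.
#' @param network a [gene_network()] (microarrays measure every mRNA).
#' @param costs a [cost_table()].
#' @return records vended divided by credits charged.
#' @export
data_points_per_credit <- function(purchase_type, network,
                                   costs = cost_table()) {
  G <- length(network$genes)
  points <- switch(purchase_type, protein_pair = 80, ma_high = 20 * G,
                   ma_low = 10 * G, gelshift = 2,
                   stop("unknown purchase type"))
  cost <- costs$readout[[purchase_type]]
  if (!is.finite(cost) || cost <= 0) stop("purchase type has no positive cost")
  points / cost
}

#' Distance between estimated and true parameters
#'
#' Sum over parameters of squared log10 deviations (default) — a parameter
#' off by a factor of 10 contributes 1 — or of absolute log10 deviations.
#'
#' @param theta_hat,theta_true named log10 parameter vectors over the same
#'   parameters.
#' @param mode `"squared"` or `"absolute"`.
#' @export
param_distance <- function(theta_hat, theta_true,
                           mode = c("squared", "absolute")) {
  mode <- match.arg(mode)
  if (length(theta_hat) != length(theta_true))
    stop("parameter vectors do not align (length mismatch)")
  if (!is.null(names(theta_hat)) && !is.null(names(theta_true))) {
    if (!all(names(theta_hat) %in% names(theta_true)))
      stop("parameter vectors do not align (name mismatch)")
    theta_true <- theta_true[names(theta_hat)]
  }
  d <- theta_hat - theta_true
  if (mode == "squared") sum(d^2) else sum(abs(d))
}

#' Mean deviation of estimates from the truth, both common readings
#'
#' The challenge-style "mean deviation in percent" is ambiguous; this
#' reports the mean absolute relative error on the linear scale (percent)
#' and the mean absolute log10 deviation.
#'
#' @inheritParams param_distance
#' @return named numeric: `percent_linear`, `mean_abs_log10`.
#' @export
mean_deviation <- function(theta_hat, theta_true) {
  if (!is.null(names(theta_hat)) && !is.null(names(theta_true)))
    theta_true <- theta_true[names(theta_hat)]
  d <- theta_hat - theta_true
  c(percent_linear = 100 * mean(abs(10^d - 1)),
    mean_abs_log10 = mean(abs(d)))
}

#' Automated benchmark of purchasing strategies
#'
#' A scripted stand-in for the interactive design loop: starting from the
#' free wildtype mRNA data, repeatedly fit, optionally profile, choose a
#' purchase by the given strategy, buy it, and refit — until the budget is
#' spent, nothing affordable remains, or `max_steps` purchases were made.
#' `greedy_R` buys the top design of the profile-spread ranking; `random`
#' buys an affordable design uniformly at random; `cheapest` always buys
#' the cheapest affordable design.
#'
#' @param G,I,seed passed to [synth_network()]; `seed` also drives the
#'   noise and all strategy randomness.
#' @param strategy `"greedy_R"`, `"random"` or `"cheapest"`.
#' @param budget starting credits (default: the cost table's).
#' @param max_steps cap on purchases.
#' @param n_starts multistart breadth of the initial fit (later refits are
#'   warm-started from the running estimate plus fresh starts).
#' @param costs,noise,horizon lab configuration.
#' @param track_identifiability compute profile ensembles (and the
#'   non-identifiability counts) even for strategies that do not need them.
#' @param profile_final profile once more after the last purchase (needed
#'   for the final non-identifiability count; the purchase decisions do not
#'   use it).
#' @param max_per_profile profile-set size per profile for scoring.
#' @param control profile stepping control.
#' @param fit_control control list for every fit in the loop (see
#'   [fit_mle()]); cap `iter.max`/`eval.max` to bound the slowest seeds.
#' @param rtol,atol solver tolerances inside the loop.
#' @param network,theta_true optional overrides of the generated truth
#'   (e.g. a fixed example topology with random truth).
#' @return data frame of class `grn_benchmark` with one row per step:
#'   `step`, `action`, `cost`, `remaining`, `nonid`, `nonid_no_hill`,
#'   `distance`. Attributes: `state` (final), `fit` (final).
#' @export
run_benchmark_loop <- function(G, I, seed, strategy = c("greedy_R",
                                                        "random",
                                                        "cheapest"),
                               budget = NULL, max_steps = Inf,
                               n_starts = 20, costs = cost_table(),
                               noise = noise_model(), horizon = 20,
                               track_identifiability =
                                 (strategy == "greedy_R"),
                               profile_final = track_identifiability,
                               max_per_profile = 5,
                               control = profile_control(max_steps = 12,
                                 target_frac = 0.25),
                               fit_control = list(),
                               rtol = 1e-6, atol = 1e-8,
                               network = NULL, theta_true = NULL) {
  strategy <- match.arg(strategy)
  truth <- synth_network(G, I, seed = seed)
  if (!is.null(network)) truth$network <- network
  if (!is.null(theta_true)) truth$theta_true <- theta_true
  if (!is.null(budget)) costs$initial_budget <- budget
  state <- challenge_init(truth$network, truth$theta_true, seed = seed,
                          costs = costs, noise = noise, horizon = horizon)
  force(track_identifiability)
  need_profiles <- strategy == "greedy_R" || track_identifiability

  rows <- list()
  th_prev <- NULL
  step <- 0L
  repeat {
    step <- step + 1L
    fixed <- if (length(state$known_params)) state$known_params
    obj <- make_objective(state$network, state$data, state$conditions,
                          noise, rtol = rtol, atol = atol)
    ms <- multistart_fit(obj,
                         n_starts = if (is.null(th_prev)) n_starts
                                    else max(1, ceiling(n_starts / 3)),
                         seed = vend_seed(state, 5000L + step),
                         fixed = fixed, extra_starts = th_prev,
                         control = fit_control)
    fit <- ms$best
    th_prev <- fit$par

    designs <- enumerate_designs(state$network, costs)
    bought_gs <- state$ledger$id[grepl("^gelshift", state$ledger$id)]
    designs <- designs[!designs$id %in% bought_gs, , drop = FALSE]
    afford <- designs[designs$cost <= state$budget, , drop = FALSE]
    done <- nrow(afford) == 0 || (step > max_steps)

    nonid <- NA_integer_; nonid_nh <- NA_integer_; ens <- NULL
    if ((strategy == "greedy_R" && !done) ||
        (need_profiles && (!done || profile_final))) {
      ens <- profile_ensemble(obj, fit, fixed = fixed, control = control)
      nonid <- count_non_identifiable(ens)
      nonid_nh <- count_non_identifiable(ens, exclude_hill = TRUE)
    }
    d <- param_distance(fit$par, truth$theta_true)
    if (!done) {
      pick <- switch(strategy,
        greedy_R = {
          stilde <- profile_parameter_set(ens, max_per_profile)
          cls <- vapply(ens$profiles, classify_identifiability,
                        character(1))
          sc <- score_designs(state$network, stilde, afford, noise,
                              theta_hat = fit$par,
                              nonid_params = names(cls)[cls !=
                                                        "identifiable"],
                              horizon = horizon, rtol = rtol, atol = atol)
          rank_designs(sc, state$budget)$recommended[1, , drop = FALSE]
        },
        random = {
          set.seed(vend_seed(state, 9000L + step))
          afford[sample.int(nrow(afford), 1), , drop = FALSE]
        },
        cheapest = afford[order(afford$cost, afford$id)[1], ,
                          drop = FALSE])
      state <- purchase(state, pick)
      action <- pick$id
      cost <- pick$cost
    } else {
      action <- "final"
      cost <- 0
    }
    rows[[step]] <- data.frame(step = step, action = action, cost = cost,
                               remaining = state$budget, nonid = nonid,
                               nonid_no_hill = nonid_nh, distance = d,
                               stringsAsFactors = FALSE)
    if (done) break
  }
  out <- do.call(rbind, rows)
  attr(out, "state") <- state
  attr(out, "fit") <- th_prev
  class(out) <- c("grn_benchmark", class(out))
  out
}
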