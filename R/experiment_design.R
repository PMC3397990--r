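#' Readout time grids for purchasable experiments
#'
#' Two-protein purchases deliver 40 points per protein; a high-density
#' microarray 20 points per mRNA; a low-density microarray 10 points per
#' mRNA. Points are evenly spaced over `(0, horizon]` (the initial state is
#' known, so t = 0 carries no information).
#'
#' @param readout_type `"protein_pair"`, `"ma_high"` or `"ma_low"`.
#' @param horizon measurement horizon (time units).
#' @return numeric vector of measurement times.
#' @export
readout_times <- function(readout_type, horizon = 20) {
  n <- switch(readout_type, protein_pair = 40, ma_high = 20, ma_low = 10,
              stop("no time grid for readout type '", readout_type, "'"))
  seq_len(n) * horizon / n
}

#' Enumerate all purchasable experiment designs
#'
#' The design space couples every perturbation condition — wildtype plus
#' knockout, siRNA knock-down and rbs doubling per gene, `3 G + 1`
#' conditions in total — with every time-course readout: each unordered
#' protein pair (`choose(G, 2)`) and two microarray densities. Gel-shift
#' experiments (one per interaction; they return the interaction's Hill
#' coefficient and Kd exactly, with no perturbation) complete the list:
#' `(3 G + 1) (choose(G, 2) + 2) + I` designs.
#'
#' @param network a [gene_network()].
#' @param costs a [cost_table()].
#' @return data frame, one design per row: `id`, `pert_kind`, `pert_gene`,
#'   `readout_type`, `readout_a`, `readout_b` (second protein, or `NA`),
#'   `interaction` (gel-shift only), `cost`.
#' @export
enumerate_designs <- function(network, costs = cost_table()) {
  g <- network$genes
  perts <- data.frame(pert_kind = "wildtype", pert_gene = NA_character_,
                      stringsAsFactors = FALSE)
  for (kind in c("knockout", "sirna", "rbs_boost"))
    perts <- rbind(perts, data.frame(pert_kind = kind, pert_gene = g,
                                     stringsAsFactors = FALSE))
  pairs <- if (length(g) >= 2) utils::combn(g, 2) else
    matrix(character(0), nrow = 2)
  readouts <- rbind(
    if (ncol(pairs)) data.frame(readout_type = "protein_pair",
                                readout_a = pairs[1, ],
                                readout_b = pairs[2, ],
                                stringsAsFactors = FALSE),
    data.frame(readout_type = c("ma_high", "ma_low"),
               readout_a = NA_character_, readout_b = NA_character_,
               stringsAsFactors = FALSE))
  tc <- merge(perts, readouts, by = NULL)
  tc$interaction <- NA_integer_
  tc$cost <- costs$readout[tc$readout_type] +
    ifelse(tc$pert_kind == "wildtype", 0,
           costs$surcharge[tc$pert_kind])
  ia <- network$interactions
  if (nrow(ia)) {
    gs <- data.frame(pert_kind = "wildtype", pert_gene = NA_character_,
                     readout_type = "gelshift", readout_a = NA_character_,
                     readout_b = NA_character_,
                     interaction = seq_len(nrow(ia)),
                     cost = costs$readout[["gelshift"]],
                     stringsAsFactors = FALSE)
    tc <- rbind(tc, gs)
  }
  tc$id <- vapply(seq_len(nrow(tc)), function(i) {
    if (tc$readout_type[i] == "gelshift")
      paste0("gelshift_", ia$from[tc$interaction[i]], "_",
             ia$to[tc$interaction[i]])
    else paste0(
      if (tc$pert_kind[i] == "wildtype") "wt"
      else paste0(tc$pert_kind[i], "_", tc$pert_gene[i]),
      ":", tc$readout_type[i],
      if (tc$readout_type[i] == "protein_pair")
        paste0("_p", tc$readout_a[i], "_p", tc$readout_b[i]) else "")
  }, character(1))
  rownames(tc) <- NULL
  tc[c("id", "pert_kind", "pert_gene", "readout_type", "readout_a",
       "readout_b", "interaction", "cost")]
}

# internal: noise-normalized spread of an ensemble of trajectories.
# arr: species x time x parameter-vectors; hat_states: the estimate's
# trajectory used as the common noise scale.
spread_score <- function(arr, hat_states, noise) {
  spread <- apply(arr, c(1, 2), max) - apply(arr, c(1, 2), min)
  spread / combined_sd(pmax(hat_states, 0), noise)
}

# internal: perturbation object and condition label of a design row
design_perturbation <- function(design) {
  if (design$pert_kind == "wildtype") perturbation("wildtype")
  else perturbation(design$pert_kind, design$pert_gene)
}

design_condition_id <- function(design) {
  if (design$pert_kind == "wildtype") "wt"
  else paste0(design$pert_kind, "_", design$pert_gene)
}

# internal: species measured by a design row
design_species <- function(design, network) {
  switch(design$readout_type,
         protein_pair = paste0("p", c(design$readout_a, design$readout_b)),
         ma_high = paste0("mRNA", network$genes),
         ma_low = paste0("mRNA", network$genes),
         stop("design has no time-course readout"))
}

#' Simulate the readout of a design for one parameter vector
#'
#' Applies the design's perturbation, integrates, and returns the
#' trajectory restricted to the readout species at the readout time grid.
#'
#' @param network a [gene_network()].
#' @param theta log10 parameter vector.
#' @param design one row of [enumerate_designs()].
#' @param horizon measurement horizon.
#' @param rtol,atol solver tolerances.
#' @return a `grn_trajectory` over the readout species and times.
#' @export
predict_readout <- function(network, theta, design, horizon = 20,
                            rtol = 1e-7, atol = 1e-9) {
  if (design$readout_type == "gelshift")
    stop("gel-shift designs have no trajectory readout")
  times <- readout_times(design$readout_type, horizon)
  tr <- simulate_grn(network, theta, times,
                     pert = design_perturbation(design),
                     rtol = rtol, atol = atol)
  sp <- design_species(design, network)
  new_trajectory(tr$times, tr$states[sp, , drop = FALSE])
}

#' Score candidate designs by profile-propagated trajectory spread
#'
#' For each design, all parameter vectors of the profile-derived set are
#' simulated under the design's perturbation; the score is the largest
#' noise-normalized spread over readout species and time points,
#' `R(D) = max_{i,t} [max_theta x_i(t) - min_theta x_i(t)] / sigma_i(t)`,
#' with `sigma_i(t)` the combined measurement s.d. evaluated on the
#' estimate's trajectory (one common scale per candidate). A summation over
#' time points is available as an alternative aggregation. Gel-shift designs
#' bypass the trajectory score: they measure two parameters exactly, so
#' they are assigned an infinite score when at least one of their
#' parameters is named in `nonid_params`, and 0 otherwise.
#'
#' @param network a [gene_network()].
#' @param stilde matrix of parameter vectors (rows, log10 scale), e.g. from
#'   [profile_parameter_set()]; the first row should be the estimate.
#' @param designs data frame from [enumerate_designs()] (any subset).
#' @param noise a [noise_model()].
#' @param theta_hat estimate used for the noise normalization; default: the
#'   first row of `stilde`.
#' @param nonid_params names of parameters currently classified
#'   non-identifiable (drives gel-shift scoring).
#' @param aggregate `"max"` (default) or `"sum"` over time points.
#' @param horizon,rtol,atol simulation settings.
#' @return `designs` with columns `R`, `argmax_species`, `argmax_time`
#'   appended, plus attribute `n_failed` (parameter vectors that failed to
#'   integrate under some condition).
#' @export
score_designs <- function(network, stilde, designs, noise = noise_model(),
                          theta_hat = NULL, nonid_params = character(),
                          aggregate = c("max", "sum"), horizon = 20,
                          rtol = 1e-7, atol = 1e-9) {
  aggregate <- match.arg(aggregate)
  if (is.null(dim(stilde))) stilde <- matrix(stilde, nrow = 1)
  if (is.null(theta_hat)) theta_hat <- stilde[1, ]
  if (nrow(stilde) < 2 && any(designs$readout_type != "gelshift"))
    stop("need at least 2 parameter vectors to measure spread")
  info <- param_info(network)
  sp <- species_names(network)

  # simulate each perturbation condition once per parameter vector
  tc <- designs[designs$readout_type != "gelshift", , drop = FALSE]
  cond_ids <- unique(vapply(seq_len(nrow(tc)), function(i)
    design_condition_id(tc[i, ]), character(1)))
  grid <- sort(unique(c(readout_times("protein_pair", horizon),
                        readout_times("ma_high", horizon),
                        readout_times("ma_low", horizon))))
  n_failed <- 0L
  cond_sims <- list()
  for (cid in cond_ids) {
    row <- tc[vapply(seq_len(nrow(tc)), function(i)
      design_condition_id(tc[i, ]) == cid, logical(1)), ][1, ]
    pert <- design_perturbation(row)
    sims <- vector("list", nrow(stilde))
    for (r in seq_len(nrow(stilde))) {
      sims[[r]] <- tryCatch(
        simulate_grn(network, stilde[r, ], grid, pert = pert,
                     rtol = rtol, atol = atol)$states,
        error = function(e) NULL)
      if (is.null(sims[[r]])) n_failed <- n_failed + 1L
    }
    hat <- tryCatch(
      simulate_grn(network, theta_hat, grid, pert = pert,
                   rtol = rtol, atol = atol)$states,
      error = function(e) NULL)
    if (all(vapply(sims, is.null, logical(1))) || is.null(hat))
      stop("no parameter vector could be simulated for condition ", cid)
    ok <- !vapply(sims, is.null, logical(1))
    arr <- simplify2array(sims[ok])            # species x time x vectors
    cond_sims[[cid]] <- list(norm = spread_score(arr, hat, noise),
                             grid = grid)
  }

  R <- numeric(nrow(designs))
  amx_sp <- character(nrow(designs)); amx_t <- rep(NA_real_, nrow(designs))
  for (i in seq_len(nrow(designs))) {
    d <- designs[i, ]
    if (d$readout_type == "gelshift") {
      ia <- network$interactions[d$interaction, ]
      pnames <- paste0(c("h_", "Kd_"), ia$from, "_", ia$to)
      R[i] <- if (any(pnames %in% nonid_params)) Inf else 0
      next
    }
    cs <- cond_sims[[design_condition_id(d)]]
    ti <- match(readout_times(d$readout_type, horizon), cs$grid)
    m <- cs$norm[design_species(d, network), ti, drop = FALSE]
    if (aggregate == "max") {
      R[i] <- max(m)
      w <- which(m == R[i], arr.ind = TRUE)[1, ]
      amx_sp[i] <- rownames(m)[w[1]]
      amx_t[i] <- cs$grid[ti][w[2]]
    } else {
      per_sp <- rowSums(m)
      R[i] <- max(per_sp)
      amx_sp[i] <- rownames(m)[which.max(per_sp)]
    }
  }
  out <- designs
  out$R <- R
  out$argmax_species <- amx_sp
  out$argmax_time <- amx_t
  attr(out, "n_failed") <- n_failed
  out
}

#' @rdname score_designs
#' @param design a single design row.
#' @export
score_design <- function(network, stilde, design, ...) {
  score_designs(network, stilde, design[1, , drop = FALSE], ...)
}

#' Rank scored designs under a budget
#'
#' Orders designs by decreasing score; among designs whose scores are
#' within 10% (relative) of each other, the cheaper one wins — cost is the
#' tie-breaker, not part of the score. Designs exceeding the remaining
#' budget are excluded from the recommendation but reported.
#'
#' @param scores output of [score_designs()].
#' @param budget remaining credits.
#' @param rel_tol relative score window regarded as a tie.
#' @return list with `recommended` (affordable designs, best first) and
#'   `excluded` (unaffordable, by score).
#' @export
rank_designs <- function(scores, budget = Inf, rel_tol = 0.1) {
  afford <- scores[scores$cost <= budget, , drop = FALSE]
  excl <- scores[scores$cost > budget, , drop = FALSE]
  order_block <- function(d) {
    if (!nrow(d)) return(d)
    d <- d[order(-d$R), , drop = FALSE]
    grp <- integer(nrow(d)); g <- 0; lead <- -Inf
    for (i in seq_len(nrow(d))) {
      tied <- i > 1 && d$R[i] >= (1 - rel_tol) * lead
      if (!tied) { g <- g + 1; lead <- d$R[i] }
      grp[i] <- g
    }
    do.call(rbind, lapply(split(d, factor(grp, levels = unique(grp))),
                          function(b) b[order(b$cost, -b$R), , drop = FALSE]))
  }
  rec <- order_block(afford)
  rownames(rec) <- NULL
  list(recommended = rec,
       excluded = excl[order(-excl$R), , drop = FALSE])
}

#' Spread of an extrapolated prediction along each parameter's profile
#'
#' Simulates the model under a prediction condition separately for each
#' parameter's profile companions and reports the noise-normalized spread
#' of the predicted trajectories, largest first: parameters whose remaining
#' uncertainty dominates the extrapolation uncertainty.
#'
#' @param network a [gene_network()].
#' @param ensemble a `grn_profile_ensemble`.
#' @param prediction_condition a [perturbation()] describing the (possibly
#'   experimentally inaccessible) condition to extrapolate to.
#' @param noise a [noise_model()].
#' @param species readout species (default: all proteins).
#' @param times prediction time grid.
#' @param rtol,atol solver tolerances.
#' @return data frame `parameter`, `spread`, sorted decreasing.
#' @export
extrapolation_uncertainty <- function(network, ensemble,
                                      prediction_condition,
                                      noise = noise_model(),
                                      species = NULL,
                                      times = readout_times("ma_high", 20),
                                      rtol = 1e-7, atol = 1e-9) {
  if (is.null(species)) species <- paste0("p", network$genes)
  theta_hat <- ensemble$fit$par
  hat <- simulate_grn(network, theta_hat, times,
                      pert = prediction_condition,
                      rtol = rtol, atol = atol)$states
  sigma <- combined_sd(pmax(hat[species, , drop = FALSE], 0), noise)
  spread <- vapply(names(ensemble$profiles), function(pn) {
    pr <- ensemble$profiles[[pn]]
    ok <- pr$grid$converged & (pr$ll_star - pr$grid$pl <= pr$delta + 1e-9)
    if (sum(ok) < 2) return(0)
    sims <- lapply(which(ok), function(i) tryCatch(
      simulate_grn(network, pr$companions[i, ], times,
                   pert = prediction_condition, rtol = rtol,
                   atol = atol)$states[species, , drop = FALSE],
      error = function(e) NULL))
    sims <- Filter(Negate(is.null), sims)
    if (length(sims) < 2) return(NA_real_)
    arr <- simplify2array(sims)
    max((apply(arr, c(1, 2), max) - apply(arr, c(1, 2), min)) / sigma)
  }, numeric(1))
  out <- data.frame(parameter = names(spread), spread = unname(spread),
                    stringsAsFactors = FALSE)
  out[order(-out$spread), ]
}

#' One step of the profile-based design loop
#'
#' Orchestrates fit, profiles, profile-derived parameter set, scoring and
#' ranking, and emits a report. Nothing is purchased automatically — the
#' final choice (and the purchase via [purchase()]) is the user's.
#'
#' @param network a [gene_network()].
#' @param data accumulated dataset.
#' @param conditions named list of perturbations covering the data.
#' @param budget remaining credits.
#' @param noise a [noise_model()].
#' @param costs a [cost_table()].
#' @param fit optional precomputed `grn_fit`/`grn_multistart` (refit
#'   otherwise).
#' @param ensemble optional precomputed profile ensemble.
#' @param fixed named log10 values of directly measured parameters.
#' @param n_starts multistart breadth when fitting here.
#' @param seed RNG seed for the multistart.
#' @param max_per_profile passed to [profile_parameter_set()].
#' @param already_purchased design ids to drop from the candidate list.
#' @param stop_spread_tol extrapolation/score level below which, with no
#'   non-identifiabilities left, the recommendation is to stop buying.
#' @param control profile control settings.
#' @param horizon,rtol,atol simulation settings.
#' @return list of class `grn_design_report`: `recommended`, `scores`,
#'   `ranking`, `nonid_count`, `nonid_params`, `stop_recommended`, `fit`,
#'   `ensemble`.
#' @export
design_step <- function(network, data, conditions, budget,
                        noise = noise_model(), costs = cost_table(),
                        fit = NULL, ensemble = NULL, fixed = NULL,
                        n_starts = 20, seed = NULL, max_per_profile = 10,
                        already_purchased = character(),
                        stop_spread_tol = 1, control = profile_control(),
                        horizon = 20, rtol = 1e-7, atol = 1e-9) {
  obj <- make_objective(network, data, conditions, noise,
                        rtol = rtol, atol = atol)
  if (is.null(fit))
    fit <- multistart_fit(obj, n_starts = n_starts, seed = seed,
                          fixed = fixed)
  if (inherits(fit, "grn_multistart")) fit <- fit$best
  if (is.null(ensemble))
    ensemble <- profile_ensemble(obj, fit, fixed = fixed, control = control)
  cls <- vapply(ensemble$profiles, classify_identifiability, character(1))
  nonid <- names(cls)[cls != "identifiable"]
  stilde <- profile_parameter_set(ensemble, max_per_profile)
  designs <- enumerate_designs(network, costs)
  designs <- designs[!designs$id %in% already_purchased, , drop = FALSE]
  scores <- score_designs(network, stilde, designs, noise,
                          theta_hat = fit$par, nonid_params = nonid,
                          horizon = horizon, rtol = rtol, atol = atol)
  ranking <- rank_designs(scores, budget)
  top <- if (nrow(ranking$recommended)) ranking$recommended[1, ] else NULL
  stop_rec <- length(nonid) == 0 &&
    (is.null(top) || max(scores$R[is.finite(scores$R)], 0) < stop_spread_tol)
  structure(list(recommended = top, scores = scores, ranking = ranking,
                 nonid_count = length(nonid), nonid_params = nonid,
                 stop_recommended = stop_rec, fit = fit,
                 ensemble = ensemble, budget = budget),
            class = "grn_design_report")
}

#' @export
print.grn_design_report <- function(x, ...) {
  cat("Design report — remaining budget:", x$budget, "credits\n")
  cat("Non-identifiable parameters:", x$nonid_count,
      if (x$nonid_count) paste0("(", paste(x$nonid_params, collapse = ", "),
                                ")"), "\n")
  if (x$stop_recommended) {
    cat("All parameters identifiable and predicted spreads are small: ",
        "recommend stopping.\n", sep = "")
  } else if (!is.null(x$recommended)) {
    cat("Recommended purchase:", x$recommended$id, "- R =",
        format(x$recommended$R, digits = 4), "for", x$recommended$cost,
        "credits\n")
  } else {
    cat("No affordable design remains.\n")
  }
  aff <- x$ranking$recommended
  if (nrow(aff)) {
    cat("Affordable designs (best first):\n")
    print(head(data.frame(id = aff$id, R = signif(aff$R, 4),
                          cost = aff$cost), 15), row.names = FALSE)
    if (nrow(aff) > 15) cat("  ...", nrow(aff) - 15, "more\n")
  }
  invisible(x)
}
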