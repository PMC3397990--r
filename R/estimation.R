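#' Latin hypercube sample of parameter vectors
#'
#' Each component's (log-scale) range is split into `n` equal strata; each
#' stratum is used exactly once per component, with uniform placement inside
#' the stratum. This spreads multi-start initial guesses so they cannot
#' cluster by chance.
#'
#' @param n number of samples.
#' @param lower,upper named numeric bounds (log10 scale), finite.
#' @param seed optional RNG seed for reproducibility.
#' @return `n x p` matrix, columns named by parameter.
#' @export
lhs_sample <- function(n, lower, upper, seed = NULL) {
  stopifnot(n >= 1, length(lower) == length(upper),
            all(is.finite(lower)), all(is.finite(upper)),
            all(upper >= lower))
  if (!is.null(seed)) set.seed(seed)
  p <- length(lower)
  out <- matrix(NA_real_, n, p, dimnames = list(NULL, names(lower)))
  for (j in seq_len(p)) {
    strata <- sample.int(n) - runif(n)             # one draw per stratum
    out[, j] <- lower[j] + (upper[j] - lower[j]) * strata / n
  }
  out
}

#' Build the negative log-likelihood objective for a network and dataset
#'
#' The returned objective maps a full log10 parameter vector to the negative
#' log-likelihood of the data over all measurement conditions, integrating
#' the model once per condition. Gradients come from forward sensitivities
#' via the chain rule (never finite differences across the solver).
#'
#' @param network a [gene_network()].
#' @param data dataset with columns `condition_id, species, time, value`.
#' @param conditions named list of [perturbation()]s; names must cover every
#'   `condition_id` in `data`. Default: a single `"wt"` wildtype condition.
#' @param noise a [noise_model()].
#' @param clip use the zero-clipped likelihood (for final fits on data
#'   containing zeros)? Default `FALSE`: the plain Gaussian form, the
#'   day-to-day objective during estimation and design.
#' @param variance `"full"` differentiates through `sigma(x(theta))` — the
#'   proper maximum-likelihood objective; `"frozen"` fixes each record's
#'   variance at the *observed* value, `sigma(y)`, giving a genuine weighted
#'   least-squares objective. The full form is skewed: because smaller model
#'   values mean smaller variance, its optimum sits slightly below the data
#'   even for noise-free data; the frozen form recovers noise-free truth
#'   exactly.
#' @param x0 optional initial-state override.
#' @param rtol,atol solver tolerances used inside the objective.
#' @return object of class `grn_objective`: list with `fn(theta)`,
#'   `gr(theta)`, `p_names`, `lower`, `upper` (default bounds) and metadata.
#' @export
make_objective <- function(network, data, conditions = NULL,
                           noise = noise_model(), clip = FALSE,
                           variance = c("full", "frozen"), x0 = NULL,
                           rtol = 1e-8, atol = 1e-10) {
  variance <- match.arg(variance)
  validate_dataset(data, clip_at_zero = clip)
  if (is.null(conditions)) {
    if (!all(data$condition_id == "wt"))
      stop("`conditions` must be given when data has non-wildtype conditions")
    conditions <- list(wt = perturbation("wildtype"))
  }
  missing <- setdiff(unique(data$condition_id), names(conditions))
  if (length(missing)) stop("conditions not defined: ",
                            paste(missing, collapse = ", "))
  info <- param_info(network)
  sp <- species_names(network)
  if (is.null(x0)) x0 <- network$initial_conditions
  bounds <- default_bounds(network)

  # precompute record layout per condition
  conds <- lapply(names(conditions), function(id) {
    d <- data[data$condition_id == id, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    times <- sort(unique(d$time))
    list(id = id, pert = conditions[[id]],
         times = times,
         sp_idx = match(d$species, sp),
         t_idx = match(d$time, times),
         y = d$value)
  })
  conds <- Filter(Negate(is.null), conds)
  for (cc in conds) {
    if (anyNA(cc$sp_idx))
      stop("unknown species in data for condition ", cc$id)
    if (any(cc$times < 0)) stop("negative measurement times")
  }

  P <- nrow(info)
  cache <- new.env(parent = emptyenv())
  cache$key <- NULL

  # Value and gradient come from one sensitivity integration per condition,
  # so the objective the optimizer accepts steps on is exactly consistent
  # with its gradient (two separate adaptive solves would differ at the
  # tolerance level and stall tight convergence).
  evaluate <- function(theta) {
    theta <- as.numeric(theta)
    if (length(theta) != P) stop("theta must have length ", P)
    if (!is.null(cache$key) && all(cache$key == theta)) return(cache$val)
    nll <- 0
    grad <- numeric(P)
    hess <- matrix(0, P, P)
    for (cc in conds) {
      rhs <- build_rhs(network, 10^theta, cc$pert)
      tr <- tryCatch(
        integrate_with_sensitivities(rhs, x0, cc$times, rtol, atol),
        grn_integration_error = function(e) NULL,
        error = function(e) NULL)
      if (is.null(tr)) {
        val <- list(nll = 1e10, grad = numeric(P), hess = diag(P),
                    failed = TRUE)
        cache$key <- theta; cache$val <- val
        return(val)
      }
      x <- tr$states[cbind(cc$sp_idx, cc$t_idx)]
      if (variance == "frozen") {
        s2 <- noise$sigma_abs^2 + (noise$sigma_rel * cc$y)^2
        r <- cc$y - x
        terms <- list(ll = -0.5 * log(2 * pi * s2) - r^2 / (2 * s2),
                      dldx = r / s2, w = 1 / s2)
      } else {
        terms <- loglik_terms(cc$y, pmax(x, 0), noise, clip = clip)
      }
      nll <- nll - sum(terms$ll)
      R <- length(cc$y)
      # records x parameters matrix of sensitivities at (species, time)
      Sm <- matrix(tr$sens[cbind(rep(cc$sp_idx, P),
                                 rep(seq_len(P), each = R),
                                 rep(cc$t_idx, P))], R, P)
      grad <- grad - drop(crossprod(Sm, terms$dldx))
      hess <- hess + crossprod(Sm * sqrt(pmax(terms$w, 0)))
    }
    if (!is.finite(nll)) nll <- 1e10
    if (any(!is.finite(hess))) hess <- diag(P)
    val <- list(nll = nll, grad = grad, hess = hess, failed = nll >= 1e9)
    cache$key <- theta; cache$val <- val
    val
  }

  structure(list(
    fn = function(theta) evaluate(theta)$nll,
    gr = function(theta) {
      g <- evaluate(theta)$grad
      g[!is.finite(g)] <- 0
      g
    },
    he = function(theta) evaluate(theta)$hess,
    p_names = info$name, lower = bounds$lower, upper = bounds$upper,
    network = network, data = data, conditions = conditions, noise = noise,
    clip = clip, x0 = x0, rtol = rtol, atol = atol),
    class = "grn_objective")
}

#' Wrap a plain function as an estimation objective
#'
#' Lets the fitting, profiling and multi-start machinery run on arbitrary
#' (negative log-likelihood) functions — handy for closed-form toy problems.
#'
#' @param fn negative log-likelihood `f(theta)`.
#' @param gr optional gradient; finite differences inside the optimizer
#'   otherwise.
#' @param lower,upper named bounds.
#' @return a `grn_objective`.
#' @export
objective_function <- function(fn, gr = NULL, lower, upper) {
  stopifnot(length(lower) == length(upper), !is.null(names(lower)))
  structure(list(fn = fn, gr = gr, p_names = names(lower),
                 lower = lower, upper = upper),
            class = "grn_objective")
}

# internal: free/fixed split
free_mask <- function(objective, fixed) {
  if (is.null(fixed)) return(rep(TRUE, length(objective$p_names)))
  unknown <- setdiff(names(fixed), objective$p_names)
  if (length(unknown)) stop("unknown fixed parameters: ",
                            paste(unknown, collapse = ", "))
  !(objective$p_names %in% names(fixed))
}

assemble_theta <- function(objective, free_values, fixed) {
  theta <- setNames(numeric(length(objective$p_names)), objective$p_names)
  theta[names(fixed)] <- unlist(fixed)
  theta[free_mask(objective, fixed)] <- free_values
  theta
}

#' Maximize the likelihood from one starting point
#'
#' Box-constrained trust-region quasi-Newton optimization (PORT routines via
#' [stats::nlminb()]) of the log-likelihood over log10 parameters, with the
#' analytic sensitivity gradient when available. Integrator failures at the
#' start yield a failed fit result rather than an error, since remote
#' corners of the parameter box routinely break the ODE solve.
#'
#' @param objective a `grn_objective`.
#' @param start named full parameter vector (log10 scale).
#' @param fixed optional named values (log10) held constant, e.g. directly
#'   measured interaction parameters.
#' @param lower,upper bounds override (full-length, log10).
#' @param control list: `iter.max` (500), `eval.max` (1000), `rel.tol`
#'   (1e-10), `x.tol` (1e-8), plus `grad.tol` (1e-3): projected-gradient
#'   infinity-norm accepted as stationary when the optimizer's own codes
#'   are inconclusive.
#' @return object of class `grn_fit`: `par` (full named log10 vector),
#'   `logLik`, `converged`, `failed`, `iterations`, `message`.
#' @export
fit_mle <- function(objective, start, fixed = NULL,
                    lower = objective$lower, upper = objective$upper,
                    control = list()) {
  ctrl <- modifyList(list(iter.max = 500, eval.max = 1000,
                          rel.tol = 1e-10, x.tol = 1e-8,
                          grad.tol = 1e-3), control)
  mask <- free_mask(objective, fixed)
  start <- start[objective$p_names]
  if (anyNA(start)) stop("start must name every parameter")
  if (!any(mask)) {  # everything fixed: nothing to optimize, just evaluate
    par <- assemble_theta(objective, numeric(0), fixed)
    val <- objective$fn(par)
    failed <- !is.finite(val) || val >= 1e9
    return(structure(list(par = par,
                          logLik = if (failed) -Inf else -val,
                          converged = !failed, failed = failed,
                          iterations = 0L, message = "all parameters fixed"),
                     class = "grn_fit"))
  }
  fn <- function(v) objective$fn(assemble_theta(objective, v, fixed))
  gr <- if (!is.null(objective$gr))
    function(v) objective$gr(assemble_theta(objective, v, fixed))[mask]
  he <- if (!is.null(objective$he))
    function(v) objective$he(assemble_theta(objective, v, fixed))[mask, mask,
                                                                  drop = FALSE]
  res <- tryCatch(
    nlminb(start[mask], fn, gradient = gr, hessian = he,
           lower = lower[objective$p_names][mask],
           upper = upper[objective$p_names][mask],
           control = ctrl[setdiff(names(ctrl), "grad.tol")]),
    error = function(e) NULL)
  if (is.null(res)) {
    return(structure(list(par = start, logLik = -Inf, converged = FALSE,
                          failed = TRUE, iterations = 0L,
                          message = "optimizer error"),
                     class = "grn_fit"))
  }
  par <- assemble_theta(objective, res$par, fixed)
  failed <- !is.finite(res$objective) || res$objective >= 1e9
  # PORT's convergence codes are pessimistic with an approximate
  # (Gauss-Newton) Hessian; accept stationarity of the projected gradient
  # as convergence at active bounds.
  converged <- !failed && res$convergence == 0
  if (!failed && !converged && !is.null(objective$gr)) {
    g <- objective$gr(par)[mask]
    lo <- lower[objective$p_names][mask]; up <- upper[objective$p_names][mask]
    at_lo <- res$par <= lo + 1e-10; at_up <- res$par >= up - 1e-10
    g[at_lo] <- pmin(g[at_lo], 0)
    g[at_up] <- pmax(g[at_up], 0)
    converged <- max(abs(g)) <= ctrl$grad.tol
  }
  structure(list(par = par, logLik = if (failed) -Inf else -res$objective,
                 converged = converged,
                 failed = failed, iterations = res$iterations,
                 message = res$message),
            class = "grn_fit")
}

#' @export
print.grn_fit <- function(x, ...) {
  cat("grn_fit: logLik =", format(x$logLik),
      if (x$failed) "(FAILED)" else if (x$converged) "(converged)"
      else "(not converged)",
      "after", x$iterations, "iterations\n")
  invisible(x)
}

#' Joint chi-square acceptance threshold for competing optima
#'
#' The 95% quantile of the chi-square distribution with degrees of freedom
#' equal to the number of free parameters, on the `-2 log L` scale: a local
#' optimum whose `2 * (LL* - LL)` exceeds this is statistically
#' distinguishable from the best fit.
#'
#' @param n_par number of free parameters.
#' @param level confidence level (default 0.95).
#' @export
cluster_threshold <- function(n_par, level = 0.95) qchisq(level, df = n_par)

#' Multi-start maximum-likelihood estimation
#'
#' Runs [fit_mle()] from `n_starts` latin-hypercube starting points,
#' clusters the resulting optima in parameter space, and reports whether a
#' single optimum survives the joint chi-square threshold
#' ([cluster_threshold()]) — i.e. whether any competing local optimum is
#' statistically compatible with the best one.
#'
#' @inheritParams fit_mle
#' @param n_starts number of latin-hypercube starts.
#' @param seed RNG seed for the start sample.
#' @param extra_starts optional matrix of additional start rows (e.g. the
#'   previous estimate when refitting after a purchase).
#' @param cluster_tol parameter-space radius (log10 units, max-norm) merging
#'   optima into one cluster.
#' @return object of class `grn_multistart`: `fits` (sorted by decreasing
#'   log-likelihood), `best`, `logLik`, `cluster` labels, `threshold`,
#'   `unique_optimum`.
#' @export
multistart_fit <- function(objective, n_starts = 100, seed = NULL,
                           fixed = NULL, lower = objective$lower,
                           upper = objective$upper, control = list(),
                           extra_starts = NULL, cluster_tol = 0.1) {
  stopifnot(n_starts >= 1)
  lo <- lower[objective$p_names]; up <- upper[objective$p_names]
  starts <- lhs_sample(n_starts, lo, up, seed = seed)
  if (!is.null(extra_starts)) {
    extra_starts <- matrix(extra_starts, ncol = length(objective$p_names),
                           dimnames = list(NULL, objective$p_names))
    starts <- rbind(extra_starts, starts)
  }
  fits <- lapply(seq_len(nrow(starts)), function(i) {
    f <- fit_mle(objective, setNames(starts[i, ], objective$p_names),
                 fixed = fixed, lower = lower, upper = upper,
                 control = control)
    f$start_index <- i
    f
  })
  ll <- vapply(fits, function(f) f$logLik, numeric(1))
  ord <- order(-ll)
  fits <- fits[ord]; ll <- ll[ord]
  if (!any(is.finite(ll))) stop("all starts failed")

  mask <- free_mask(objective, fixed)
  cluster <- rep(NA_integer_, length(fits))
  reps <- list()
  for (i in seq_along(fits)) {
    if (!is.finite(ll[i])) next
    assigned <- FALSE
    for (k in seq_along(reps)) {
      if (max(abs(fits[[i]]$par[mask] - reps[[k]][mask])) <= cluster_tol) {
        cluster[i] <- k; assigned <- TRUE; break
      }
    }
    if (!assigned) {
      reps[[length(reps) + 1]] <- fits[[i]]$par
      cluster[i] <- length(reps)
    }
  }
  thr <- cluster_threshold(sum(mask))
  below <- unique(cluster[is.finite(ll) & 2 * (ll[1] - ll) <= thr])
  structure(list(fits = fits, best = fits[[1]], logLik = ll[1],
                 cluster = cluster, threshold = thr,
                 clusters_below_threshold = length(below),
                 unique_optimum = length(below) == 1,
                 n_converged = sum(vapply(fits, function(f)
                   isTRUE(f$converged), logical(1)))),
            class = "grn_multistart")
}

#' @export
print.grn_multistart <- function(x, ...) {
  cat("grn_multistart:", length(x$fits), "starts,", x$n_converged,
      "converged; best logLik =", format(x$logLik), "\n",
      x$clusters_below_threshold,
      "optimum cluster(s) below the joint chi-square threshold\n")
  invisible(x)
}

#' Sorted log-likelihoods of a multi-start (waterfall values)
#'
#' @param multistart a `grn_multistart`.
#' @return numeric vector of log-likelihoods, decreasing.
#' @export
waterfall <- function(multistart) {
  vapply(multistart$fits, function(f) f$logLik, numeric(1))
}
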