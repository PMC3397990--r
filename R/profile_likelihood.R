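#' Profiling control parameters
#'
#' The profiler steps a parameter away from its estimate, re-optimizing all
#' others at each grid point (warm-started from the previous companion
#' vector). The step size adapts so each step lowers the profile by roughly
#' `target_frac` of the confidence threshold, halving on overshoot, and is
#' capped at `step_max` log10 units.
#'
#' @param step_init initial step (log10 units).
#' @param step_max,step_min step caps (log10 units).
#' @param target_frac target profile drop per step, as a fraction of the
#'   threshold.
#' @param max_steps maximum grid points per direction.
#' @param reopt_control control list passed to the re-optimizations.
#' @export
profile_control <- function(step_init = 0.05, step_max = 0.2,
                            step_min = 1e-4, target_frac = 0.1,
                            max_steps = 50, reopt_control = list(
                              iter.max = 100, eval.max = 200)) {
  list(step_init = step_init, step_max = step_max, step_min = step_min,
       target_frac = target_frac, max_steps = max_steps,
       reopt_control = reopt_control)
}

#' Profile likelihood of one parameter
#'
#' Fixes parameter `index` on a grid around its maximum-likelihood value and
#' re-maximizes the likelihood over all remaining parameters at each grid
#' point. Profiling stops in each direction once the profile has dropped
#' below the confidence threshold (`qchisq(alpha, 1) / 2` log-likelihood
#' units below the optimum) or a parameter bound is reached. Grid points
#' where the re-optimization fails are flagged and skipped over.
#'
#' @param objective a `grn_objective`.
#' @param fit a `grn_fit` (or `grn_multistart`) at a converged optimum.
#' @param index parameter name (or position).
#' @param alpha confidence level for the stopping threshold.
#' @param fixed named log10 values held constant throughout (these are not
#'   profiled companions but hard constraints, e.g. directly measured
#'   parameters).
#' @param lower,upper bounds (full-length, log10).
#' @param control a [profile_control()] list.
#' @return object of class `grn_profile`: `grid` data frame
#'   (`value`, `pl`, `converged`), `companions` matrix (one full parameter
#'   vector per grid row), `theta_hat`, `ll_star`, `delta`
#'   (threshold on the log-likelihood scale), `hit_lower`, `hit_upper`.
#' @export
profile_likelihood <- function(objective, fit, index, alpha = 0.95,
                               fixed = NULL, lower = objective$lower,
                               upper = objective$upper,
                               control = profile_control()) {
  if (inherits(fit, "grn_multistart")) fit <- fit$best
  stopifnot(inherits(fit, "grn_fit"))
  pn <- objective$p_names
  if (is.character(index)) index <- match(index, pn)
  stopifnot(!is.na(index), index >= 1, index <= length(pn))
  name <- pn[index]
  if (name %in% names(fixed)) stop("cannot profile a fixed parameter")
  theta_hat <- fit$par[pn]
  ll_star <- fit$logLik
  delta <- qchisq(alpha, df = 1) / 2
  lo <- lower[pn]; up <- upper[pn]

  # curvature-scaled initial step: a quarter of the expected Wald-type
  # half-width; non-identifiable directions (huge or failed curvature)
  # fall back to the step cap.
  step0 <- control$step_init
  if (!is.null(objective$he)) {
    mask <- free_mask(objective, fixed)
    se <- tryCatch({
      H <- objective$he(theta_hat)[mask, mask, drop = FALSE]
      sqrt(diag(solve(H)))[match(index, which(mask))]
    }, error = function(e) NA_real_)
    if (is.finite(se) && se > 0)
      step0 <- min(max(se * sqrt(2 * delta) / 4, control$step_min),
                   control$step_max)
    else step0 <- control$step_max
  }

  one_direction <- function(dir) {
    value <- numeric(0); pl <- numeric(0); conv <- logical(0)
    comp <- list()
    v <- theta_hat[[index]]
    companion <- theta_hat
    last_pl <- ll_star
    step <- step0
    hit_bound <- FALSE
    target <- control$target_frac * delta
    for (k in seq_len(control$max_steps)) {
      v_new <- v + dir * step
      at_bound <- FALSE
      if (v_new <= lo[[index]]) { v_new <- lo[[index]]; at_bound <- TRUE }
      if (v_new >= up[[index]]) { v_new <- up[[index]]; at_bound <- TRUE }
      if (v_new == v) { hit_bound <- TRUE; break }
      fx <- c(fixed, setNames(v_new, name))
      start <- companion; start[[index]] <- v_new
      rf <- fit_mle(objective, start, fixed = fx, lower = lower,
                    upper = upper, control = control$reopt_control)
      value <- c(value, v_new); pl <- c(pl, rf$logLik)
      conv <- c(conv, !rf$failed)
      comp[[length(comp) + 1]] <- rf$par
      if (!rf$failed) {
        drop_step <- last_pl - rf$logLik
        crossed <- ll_star - rf$logLik > delta
        if (crossed) {
          # refine towards the crossing instead of leaving a coarse gap
          if (ll_star - rf$logLik > 1.3 * delta &&
              step > 4 * control$step_min) {
            step <- step / 2
            next  # re-step from the same v with a finer step
          }
          break
        }
        v <- v_new
        companion <- rf$par
        last_pl <- rf$logLik
        fac <- if (is.finite(drop_step) && abs(drop_step) > 1e-12)
          target / abs(drop_step) else 2
        if (drop_step > 1.5 * target) fac <- min(fac, 0.5)  # overshoot
        step <- min(max(step * min(max(fac, 0.5), 2), control$step_min),
                    control$step_max)
      } else {
        v <- v_new  # flagged point; keep walking
      }
      if (at_bound) { hit_bound <- TRUE; break }
    }
    ord <- order(if (dir < 0) -value else value)
    list(value = value[ord], pl = pl[ord], conv = conv[ord],
         comp = comp[ord], hit_bound = hit_bound)
  }

  dn <- one_direction(-1)
  up_ <- one_direction(+1)
  value <- c(rev(dn$value), theta_hat[[index]], up_$value)
  pl <- c(rev(dn$pl), ll_star, up_$pl)
  conv <- c(rev(dn$conv), TRUE, up_$conv)
  comp <- do.call(rbind, c(rev(dn$comp), list(theta_hat), up_$comp))
  colnames(comp) <- pn
  structure(list(parameter = name, index = index, alpha = alpha,
                 delta = delta, ll_star = ll_star, theta_hat = theta_hat,
                 grid = data.frame(value = value, pl = pl,
                                   converged = conv),
                 companions = comp,
                 hit_lower = dn$hit_bound, hit_upper = up_$hit_bound,
                 lower = lo[[index]], upper = up[[index]]),
            class = "grn_profile")
}

#' @export
print.grn_profile <- function(x, ...) {
  ci <- confidence_interval(x)
  cat("grn_profile of", x$parameter, "(", nrow(x$grid), "points):",
      classify_identifiability(x), "\n  CI:",
      if (ci$open_lower) "(open" else paste0("[", format(ci$lower)), ",",
      if (ci$open_upper) "open)" else paste0(format(ci$upper), "]"), "\n")
  invisible(x)
}

#' Likelihood-based confidence interval from a profile
#'
#' The interval is the set of parameter values whose profile log-likelihood
#' stays within `qchisq(alpha, 1) / 2` of the optimum; crossings are found
#' by linear interpolation on the profile grid. A side is open-ended when
#' the profile reaches the parameter bound while still above the threshold.
#'
#' @param profile a `grn_profile`.
#' @param alpha confidence level; must not exceed the level the profile was
#'   traced at (the profile stops at its own threshold).
#' @return list with `lower`, `upper`, `open_lower`, `open_upper`.
#' @export
confidence_interval <- function(profile, alpha = profile$alpha) {
  delta <- qchisq(alpha, df = 1) / 2
  thr <- profile$ll_star - delta
  g <- profile$grid[profile$grid$converged, , drop = FALSE]
  hat <- profile$theta_hat[[profile$index]]

  side <- function(sub, bound_hit, bound_val) {
    # sub ordered from theta_hat outward; first row is theta_hat itself
    below <- which(sub$pl < thr)
    if (length(below)) {
      i <- below[1]
      if (i == 1) return(list(value = sub$value[1], open = FALSE))
      # interpolate on the sqrt of the log-likelihood drop: exact for a
      # quadratic profile centred at the estimate
      ll0 <- max(sub$pl[1], profile$ll_star)
      d1 <- sqrt(max(ll0 - sub$pl[i - 1], 0))
      d2 <- sqrt(max(ll0 - sub$pl[i], 0))
      dstar <- sqrt(ll0 - thr)
      t <- if (d2 > d1) (dstar - d1) / (d2 - d1) else
        (sub$pl[i - 1] - thr) / (sub$pl[i - 1] - sub$pl[i])
      t <- min(max(t, 0), 1)
      list(value = sub$value[i - 1] + t * (sub$value[i] - sub$value[i - 1]),
           open = FALSE)
    } else if (bound_hit || (nrow(sub) &&
               (abs(sub$value[nrow(sub)] - bound_val) < 1e-12))) {
      list(value = bound_val, open = TRUE)
    } else {
      # profile ended (step budget) without crossing: treat as open
      list(value = if (nrow(sub)) sub$value[nrow(sub)] else hat, open = TRUE)
    }
  }
  i_hat <- which.min(abs(g$value - hat))
  lo <- side(g[seq(i_hat, 1), , drop = FALSE], profile$hit_lower,
             profile$lower)
  hi <- side(g[seq(i_hat, nrow(g)), , drop = FALSE], profile$hit_upper,
             profile$upper)
  list(lower = lo$value, upper = hi$value,
       open_lower = lo$open, open_upper = hi$open)
}

#' Identifiability classification from a profile shape
#'
#' * `identifiable`: both confidence-interval ends are interior crossings.
#' * `practically_non_identifiable`: the profile reaches at least one
#'   parameter bound while still above the threshold (the data bound the
#'   parameter on one side only, or the step budget ran out before a
#'   crossing), but the profile is not flat.
#' * `structurally_non_identifiable`: the profile is flat to within
#'   `flat_tol` log-likelihood units across the explored domain.
#'
#' @param profile a `grn_profile`.
#' @param flat_tol flatness tolerance (log-likelihood units).
#' @return character scalar.
#' @export
classify_identifiability <- function(profile, flat_tol = 1e-3) {
  g <- profile$grid[profile$grid$converged, , drop = FALSE]
  flat <- (max(g$pl) - min(g$pl)) < flat_tol
  if (flat && profile$hit_lower && profile$hit_upper)
    return("structurally_non_identifiable")
  ci <- confidence_interval(profile)
  if (!ci$open_lower && !ci$open_upper) "identifiable"
  else "practically_non_identifiable"
}

#' Profile every parameter
#'
#' @inheritParams profile_likelihood
#' @param params parameter names to profile (default: all free parameters).
#' @return object of class `grn_profile_ensemble`: named list `profiles`,
#'   plus the fit, level and parameter bookkeeping.
#' @export
profile_ensemble <- function(objective, fit, alpha = 0.95, params = NULL,
                             fixed = NULL, lower = objective$lower,
                             upper = objective$upper,
                             control = profile_control()) {
  if (inherits(fit, "grn_multistart")) fit <- fit$best
  if (is.null(params))
    params <- setdiff(objective$p_names, names(fixed))
  profiles <- lapply(params, function(pn)
    profile_likelihood(objective, fit, pn, alpha = alpha, fixed = fixed,
                       lower = lower, upper = upper, control = control))
  names(profiles) <- params
  info <- if (!is.null(objective$network)) param_info(objective$network)
  structure(list(profiles = profiles, fit = fit, alpha = alpha,
                 fixed = fixed, p_info = info),
            class = "grn_profile_ensemble")
}

#' @export
print.grn_profile_ensemble <- function(x, ...) {
  cls <- vapply(x$profiles, classify_identifiability, character(1))
  cat("grn_profile_ensemble:", length(x$profiles), "profiles at alpha =",
      x$alpha, "\n")
  print(table(cls))
  invisible(x)
}

#' Count non-identifiable parameters in a profile ensemble
#'
#' Counts parameters classified as practically or structurally
#' non-identifiable. Hill coefficients can be excluded: their domain is
#' deliberately narrow, so a true value at the boundary creates a profile
#' minimum at the border that mimics a non-identifiability.
#'
#' @param ensemble a `grn_profile_ensemble`.
#' @param exclude_hill drop Hill-coefficient parameters from the count?
#' @param flat_tol passed to [classify_identifiability()].
#' @return integer count.
#' @export
count_non_identifiable <- function(ensemble, exclude_hill = FALSE,
                                   flat_tol = 1e-3) {
  keep <- names(ensemble$profiles)
  if (exclude_hill && !is.null(ensemble$p_info)) {
    hills <- ensemble$p_info$name[ensemble$p_info$type == "hill"]
    keep <- setdiff(keep, hills)
  }
  cls <- vapply(ensemble$profiles[keep], classify_identifiability,
                character(1), flat_tol = flat_tol)
  sum(cls != "identifiable")
}

#' Profile-derived parameter set for experimental design
#'
#' Pools companion parameter vectors along all profiles that lie within the
#' confidence threshold of the optimum: the finite stand-in for the set of
#' parameter vectors statistically compatible with the current data. Always
#' contains the maximum-likelihood estimate; per profile, up to
#' `max_per_profile` additional vectors evenly spaced along the profile
#' grid.
#'
#' @param ensemble a `grn_profile_ensemble`.
#' @param max_per_profile cap on vectors taken from each profile (the
#'   estimate itself not counted).
#' @return matrix, one parameter vector (log10) per row; first row is the
#'   estimate.
#' @export
profile_parameter_set <- function(ensemble, max_per_profile = 10) {
  theta_hat <- ensemble$fit$par
  rows <- list(theta_hat)
  for (pr in ensemble$profiles) {
    ok <- pr$grid$converged & (pr$ll_star - pr$grid$pl <= pr$delta + 1e-9)
    idx <- which(ok)
    if (!length(idx) || max_per_profile <= 1) next
    pick <- unique(round(seq(1, length(idx),
                             length.out = min(max_per_profile, length(idx)))))
    rows <- c(rows, lapply(idx[pick], function(i) pr$companions[i, ]))
  }
  out <- do.call(rbind, rows)
  out[!duplicated(round(out, 10)), , drop = FALSE]
}
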