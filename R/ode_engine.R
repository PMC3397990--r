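#' Integrate an ODE system with an adaptive stiff Rosenbrock method
#'
#' Solves `dx/dt = f(x)` from `t = 0` with an L-stable, adaptive-step
#' Rosenbrock(2,3) scheme. Gene-network right-hand sides built by
#' [build_rhs()] use a compiled kernel with analytic Jacobians; arbitrary R
#' functions fall back to a pure-R implementation of the same scheme with a
#' finite-difference state Jacobian.
#'
#' @param rhs vector field: a `grn_rhs` from [build_rhs()] or a function
#'   `f(x)`.
#' @param x0 non-negative initial state (named for `grn_rhs`).
#' @param times strictly increasing output times, `>= 0`.
#' @param rtol,atol relative/absolute step-error tolerances.
#' @param maxsteps cap on internal steps before the solver gives up.
#' @param method `"auto"` (default: the explicit Dormand-Prince 5(4) pair,
#'   falling back to the stiff Rosenbrock when it runs out of steps),
#'   `"ros23"` (adaptive L-stable Rosenbrock, robust on stiff parameter
#'   corners) or `"dopri5"`.
#' @return object of class `grn_trajectory`: list with `times`, `states`
#'   (species x time matrix), and for [integrate_with_sensitivities()] also
#'   `sens` (species x parameter x time array of d x / d log10 theta).
#' @seealso [simulate_grn()] for the one-call network interface.
#' @export
integrate_ode <- function(rhs, x0, times, rtol = 1e-8, atol = 1e-10,
                          maxsteps = 200000L,
                          method = c("auto", "ros23", "dopri5")) {
  check_times(times)
  stopifnot(rtol > 0, atol > 0)
  method <- match.arg(method)
  if (inherits(rhs, "grn_rhs"))
    return(grn_integrate(rhs, x0, times, rtol, atol, sens = FALSE, maxsteps,
                         method))
  if (any(x0 < 0)) stop("initial state must be non-negative")
  states <- ros23_r(rhs, as.numeric(x0), times, rtol, atol, maxsteps)
  rownames(states) <- names(x0)
  new_trajectory(times, states)
}

#' @rdname integrate_ode
#' @details Sensitivities `S = d x / d log10(theta)` solve the forward
#'   system `dS/dt = (df/dx) S + df/dlog10(theta)` with `S(0) = 0`; they are
#'   propagated simultaneously with the states and are only available for
#'   compiled `grn_rhs` models, whose Jacobians are analytic (finite
#'   differences across an adaptive integrator are not reliable).
#' @export
integrate_with_sensitivities <- function(rhs, x0, times, rtol = 1e-8,
                                         atol = 1e-10, maxsteps = 200000L,
                                         method = c("auto", "ros23",
                                                    "dopri5")) {
  check_times(times)
  stopifnot(rtol > 0, atol > 0)
  method <- match.arg(method)
  if (!inherits(rhs, "grn_rhs"))
    stop("sensitivity integration needs a compiled `grn_rhs` model ",
         "(analytic Jacobians); got a plain function")
  grn_integrate(rhs, x0, times, rtol, atol, sens = TRUE, maxsteps, method)
}

#' Simulate a gene network under a perturbation
#'
#' Convenience wrapper: applies the perturbation, builds the right-hand
#' side and integrates from the network's initial conditions.
#'
#' @inheritParams apply_perturbation
#' @inheritParams integrate_ode
#' @param theta parameter vector on the **log10** scale (the estimation
#'   scale), named as in [param_info()].
#' @param sensitivities if `TRUE`, also propagate forward sensitivities
#'   w.r.t. log10 parameters.
#' @param x0 optional initial state override.
#' @export
simulate_grn <- function(network, theta, times,
                         pert = perturbation("wildtype"), x0 = NULL,
                         sensitivities = FALSE, rtol = 1e-8, atol = 1e-10,
                         maxsteps = 200000L,
                         method = c("auto", "ros23", "dopri5")) {
  method <- match.arg(method)
  rhs <- build_rhs(network, 10^theta, pert)
  if (is.null(x0)) x0 <- network$initial_conditions
  if (sensitivities)
    integrate_with_sensitivities(rhs, x0, times, rtol, atol, maxsteps,
                                 method)
  else integrate_ode(rhs, x0, times, rtol, atol, maxsteps, method)
}

check_times <- function(times) {
  if (!length(times) || any(times < 0) || is.unsorted(times, strictly = TRUE))
    stop("`times` must be strictly increasing and non-negative")
}

new_trajectory <- function(times, states, sens = NULL) {
  structure(list(times = times, states = states, sens = sens),
            class = "grn_trajectory")
}

#' @export
print.grn_trajectory <- function(x, ...) {
  cat("grn_trajectory:", nrow(x$states), "species at", length(x$times),
      "times in [", min(x$times), ",", max(x$times), "]",
      if (!is.null(x$sens)) "(with sensitivities)", "\n")
  invisible(x)
}

#' @export
as.data.frame.grn_trajectory <- function(x, ...) {
  data.frame(species = rep(rownames(x$states), times = length(x$times)),
             time = rep(x$times, each = nrow(x$states)),
             value = as.vector(x$states), stringsAsFactors = FALSE)
}

#' Write a trajectory to CSV (species, time, value)
#'
#' @param trajectory a `grn_trajectory`.
#' @param path file path.
#' @export
write_trajectory <- function(trajectory, path) {
  write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}

# fast path: compiled GRN kernel
grn_integrate <- function(rhs, x0, times, rtol, atol, sens, maxsteps,
                          method = "auto") {
  net <- attr(rhs, "network")
  enc <- attr(rhs, "encoding")
  theta <- attr(rhs, "theta")
  dm <- attr(rhs, "dm")
  sp <- species_names(net)
  if (!is.null(names(x0))) x0 <- x0[sp]
  if (length(x0) != length(sp)) stop("unknown or missing species in x0")
  if (any(is.na(x0))) stop("unknown or missing species in x0")
  if (any(x0 < 0)) stop("initial state must be non-negative")
  call_cpp <- function(meth, msteps)
    grn_integrate_cpp(enc$G, enc$tg, enc$rg, enc$sg, unname(theta),
                      unname(dm), unname(net$basal), as.numeric(x0),
                      as.numeric(times), rtol, atol, sens,
                      hmax = max(times) / 2, maxsteps = msteps,
                      method = if (meth == "ros23") 0L else 1L,
                      err_sens = FALSE)
  res <- switch(method,
    ros23 = call_cpp("ros23", maxsteps),
    dopri5 = call_cpp("dopri5", maxsteps),
    auto = {
      r <- call_cpp("dopri5", min(maxsteps, 30000L))
      if (!r$success) r <- call_cpp("ros23", maxsteps)
      r
    })
  if (!res$success)
    stop(grn_integration_error(res$t_fail))
  states <- res$states
  rownames(states) <- sp
  s <- NULL
  if (sens) {
    s <- res$sens
    dimnames(s) <- list(sp, names(theta), NULL)
  }
  new_trajectory(times, states, s)
}

grn_integration_error <- function(t_fail) {
  structure(class = c("grn_integration_error", "error", "condition"),
            list(message = paste0("ODE integration failed at t = ",
                                  format(t_fail)),
                 call = NULL, t_fail = t_fail))
}

# Pure-R Rosenbrock(2,3) for arbitrary autonomous f(x); finite-difference
# Jacobian, refreshed every accepted step. Used for toy problems and as an
# independent cross-check of the compiled kernel.
ros23_r <- function(f, x0, times, rtol, atol, maxsteps) {
  n <- length(x0)
  d <- 1 / (2 + sqrt(2))
  e32 <- 6 + sqrt(2)
  numjac <- function(x, fx) {
    J <- matrix(0, n, n)
    for (i in seq_len(n)) {
      dx <- 1e-7 * max(abs(x[i]), 1e-4)
      xp <- x; xp[i] <- xp[i] + dx
      J[, i] <- (f(xp) - fx) / dx
    }
    J
  }
  out <- matrix(NA_real_, n, length(times))
  t <- 0; x <- x0; it <- 1
  while (it <= length(times) && times[it] <= t + 1e-14) {
    out[, it] <- x; it <- it + 1
  }
  if (it > length(times)) return(out)
  tend <- max(times)
  h <- min(tend * 1e-3, tend - t)
  f0 <- f(x); J <- numjac(x, f0)
  nsteps <- 0
  while (t < tend) {
    nsteps <- nsteps + 1
    if (nsteps > maxsteps || h < 16 * .Machine$double.eps * max(abs(t), 1))
      stop(grn_integration_error(t))
    hfull <- h
    hit <- FALSE
    if (t + h >= times[it] - 1e-14) { h <- times[it] - t; hit <- TRUE }
    W <- diag(n) - h * d * J
    k1 <- tryCatch(solve(W, f0), error = function(e) NULL)
    if (is.null(k1)) { h <- hfull / 2; next }
    fmid <- f(x + 0.5 * h * k1)
    k2 <- solve(W, fmid - k1) + k1
    x1 <- x + h * k2
    f2 <- f(x1)
    if (any(!is.finite(f2))) { h <- hfull / 2; next }
    k3 <- solve(W, f2 - e32 * (k2 - fmid) - 2 * (k1 - f0))
    err <- (h / 6) * (k1 - 2 * k2 + k3)
    sc <- atol + rtol * pmax(abs(x), abs(x1))
    errnorm <- max(abs(err) / sc)
    if (is.finite(errnorm) && errnorm <= 1) {
      t <- t + h; x <- x1
      f0 <- f2; J <- numjac(x, f0)
      while (it <= length(times) && times[it] <= t + 1e-12) {
        out[, it] <- x; it <- it + 1
      }
      if (it > length(times)) break
      hnew <- h * min(5, max(0.2, 0.8 * max(errnorm, 1e-10)^(-1 / 3)))
      if (hit) hnew <- max(hnew, hfull)
      h <- min(hnew, tend - t + 1e-14)
    } else if (!is.finite(errnorm)) {
      h <- hfull / 2
    } else {
      h <- h * max(0.2, 0.8 * errnorm^(-1 / 3))
    }
  }
  out
}
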