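#' Measurement noise model: absolute plus relative Gaussian error
#'
#' A measurement of a true level `x` is
#' `y = max(0, x + e_abs + e_rel)` with `e_abs ~ N(0, sigma_abs^2)` and
#' `e_rel ~ N(0, (sigma_rel * x)^2)`; the relative term scales with the
#' noise-free model value, so the two errors combine into a single Gaussian
#' with standard deviation [combined_sd()]. Negative realizations are
#' clipped to zero when `clip_at_zero` is set, which places a probability
#' atom at `y = 0`.
#'
#' @param sigma_abs absolute noise s.d. (concentration units).
#' @param sigma_rel relative noise s.d. (dimensionless; default 0.2).
#' @param clip_at_zero clip negative draws to zero?
#' @return object of class `noise_model`.
#' @export
noise_model <- function(sigma_abs = 0.1, sigma_rel = 0.2,
                        clip_at_zero = TRUE) {
  stopifnot(sigma_abs >= 0, sigma_rel >= 0)
  if (sigma_abs == 0 && sigma_rel == 0 && clip_at_zero)
    stop("at least one noise component must be positive")
  structure(list(sigma_abs = sigma_abs, sigma_rel = sigma_rel,
                 clip_at_zero = isTRUE(clip_at_zero)),
            class = "noise_model")
}

#' Combined measurement standard deviation
#'
#' `sigma(x) = sqrt(sigma_abs^2 + (sigma_rel * x)^2)` — the s.d. of the sum
#' of the independent absolute and relative Gaussian errors at true level
#' `x`.
#'
#' @param x true (noise-free) level, `>= 0`; vectorized.
#' @param noise a [noise_model()].
#' @export
combined_sd <- function(x, noise) {
  if (any(x < 0)) stop("true level must be non-negative")
  sqrt(noise$sigma_abs^2 + (noise$sigma_rel * x)^2)
}

#' Draw simulated measurements
#'
#' @inheritParams combined_sd
#' @return simulated values, clipped at zero if the model says so. Uses the
#'   R RNG; set a seed for reproducibility.
#' @export
simulate_measurement <- function(x, noise) {
  if (any(x < 0)) stop("true level must be non-negative")
  y <- x + rnorm(length(x), 0, combined_sd(x, noise))
  if (noise$clip_at_zero) y <- pmax(0, y)
  y
}

#' Measurement dataset constructor / CSV IO
#'
#' Datasets are plain data frames with columns `condition_id` (which
#' perturbation condition the record was measured under), `species`,
#' `time`, `value`.
#'
#' @param condition_id,species,time,value record columns (recycled).
#' @return data frame with the four canonical columns.
#' @export
grn_dataset <- function(condition_id, species, time, value) {
  d <- data.frame(condition_id = as.character(condition_id),
                  species = as.character(species),
                  time = as.numeric(time), value = as.numeric(value),
                  stringsAsFactors = FALSE)
  validate_dataset(d)
  d
}

validate_dataset <- function(data, clip_at_zero = TRUE) {
  need <- c("condition_id", "species", "time", "value")
  missing <- setdiff(need, names(data))
  if (length(missing)) stop("dataset lacks columns: ",
                            paste(missing, collapse = ", "))
  if (clip_at_zero && any(data$value < 0))
    stop("negative observed values are inconsistent with zero-clipped noise")
  invisible(data)
}

#' @rdname grn_dataset
#' @param path CSV file path.
#' @export
read_dataset <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  validate_dataset(d, clip_at_zero = FALSE)
  d
}

#' @rdname grn_dataset
#' @param data dataset data frame.
#' @export
write_dataset <- function(data, path) {
  write.csv(data, path, row.names = FALSE)
  invisible(path)
}

# internal: pick model values x at each record's (species, time) from a
# trajectory; error if a record is not on the simulated grid.
align_records <- function(data, trajectory, tol = 1e-8) {
  si <- match(data$species, rownames(trajectory$states))
  if (anyNA(si)) stop("dataset species not in trajectory: ",
                      paste(unique(data$species[is.na(si)]), collapse = ", "))
  ti <- vapply(data$time, function(t) {
    j <- which.min(abs(trajectory$times - t))
    if (abs(trajectory$times[j] - t) > tol) NA_integer_ else j
  }, integer(1))
  if (anyNA(ti)) stop("dataset times missing from trajectory grid")
  cbind(species = si, time = ti)
}

#' Gaussian log-likelihood of a dataset given a trajectory
#'
#' The unclipped form: each record contributes
#' `log N(y; x, sigma(x)^2)` with `sigma` from [combined_sd()] evaluated at
#' the model value `x` — including the `-log sigma - log(2*pi)/2` terms,
#' which matter because `sigma` depends on the parameters through `x`.
#'
#' @param data dataset (see [grn_dataset()]); single condition — its records
#'   must all be simulated by `trajectory`.
#' @param trajectory a `grn_trajectory` containing every record's
#'   (species, time).
#' @param noise a [noise_model()].
#' @return total log-likelihood (scalar).
#' @export
loglik_gaussian <- function(data, trajectory, noise) {
  idx <- align_records(data, trajectory)
  x <- trajectory$states[idx]
  sum(dnorm(data$value, mean = x, sd = combined_sd(x, noise), log = TRUE))
}

#' Zero-clipped log-likelihood
#'
#' Records with `y > 0` contribute the Gaussian density term of
#' [loglik_gaussian()]; records with `y = 0` contribute the log probability
#' mass of clipping, `log Phi(-x / sigma(x))`. On a dataset without zeros
#' this reduces exactly to the unclipped form.
#'
#' @inheritParams loglik_gaussian
#' @export
loglik_clipped <- function(data, trajectory, noise) {
  validate_dataset(data, clip_at_zero = TRUE)
  idx <- align_records(data, trajectory)
  x <- trajectory$states[idx]
  s <- combined_sd(x, noise)
  zero <- data$value == 0
  sum(dnorm(data$value[!zero], mean = x[!zero], sd = s[!zero], log = TRUE)) +
    sum(pnorm(-x[zero] / s[zero], log.p = TRUE))
}

# internal: per-record log-likelihood contributions and their derivatives
# w.r.t. the model value x. Used by the estimation objective.
#  unclipped record: l = -log s - log(2 pi)/2 - (y - x)^2 / (2 s^2)
#   dl/dx = (y - x)/s^2 + [ (y - x)^2 / s^2 - 1 ] * sr^2 x / s^2
#  clipped zero record: l = log Phi(-x/s);  d(x/s)/dx = sa^2 / s^3
# Also returns w, the per-record Gauss-Newton curvature weight
# (E[-d^2 l/dx^2] to leading order), used to build the Hessian
# approximation for the trust-region optimizer.
loglik_terms <- function(y, x, noise, clip = FALSE) {
  s2 <- noise$sigma_abs^2 + (noise$sigma_rel * x)^2
  s <- sqrt(s2)
  r <- y - x
  ll <- -log(s) - 0.5 * log(2 * pi) - r^2 / (2 * s2)
  dldx <- r / s2 + (r^2 / s2 - 1) * noise$sigma_rel^2 * x / s2
  w <- 1 / s2 + 2 * (noise$sigma_rel^2 * x / s2)^2
  if (clip) {
    zero <- y == 0
    if (any(zero)) {
      z <- -x[zero] / s[zero]
      ll[zero] <- pnorm(z, log.p = TRUE)
      # d/dx log Phi(-x/s) = -phi(z)/Phi(z) * sa^2 / s^3
      hr <- exp(dnorm(z, log = TRUE) - pnorm(z, log.p = TRUE))
      dzdx <- noise$sigma_abs^2 / s[zero]^3
      dldx[zero] <- -hr * dzdx
      w[zero] <- pmax(hr * (hr + z), 0) * dzdx^2
    }
  }
  list(ll = ll, dldx = dldx, w = w)
}
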