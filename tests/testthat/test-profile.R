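test_that("profiles of a correlated Gaussian toy match the closed form", {
  set.seed(41)
  A <- matrix(c(2, 0.8, 0.3, 0.8, 1.5, -0.4, 0.3, -0.4, 1), 3, 3)
  H <- crossprod(A)  # positive definite with correlations
  a <- c(x = 0.2, y = -0.5, z = 1)
  obj <- gaussian_objective(a, H)
  f <- fit_mle(obj, c(x = 0, y = 0, z = 0))
  se <- sqrt(diag(solve(H)))
  for (i in 1:3) {
    pr <- profile_likelihood(obj, f, names(a)[i],
                             control = fast_profile())
    # profile passes through the optimum and never exceeds it
    expect_equal(max(pr$grid$pl), pr$ll_star, tolerance = 1e-6)
    expect_true(all(pr$grid$pl <= pr$ll_star + 1e-6))
    # quadratic profile: PL(t) = LL* - (t - a_i)^2 / (2 se_i^2)
    mid <- abs(pr$grid$value - a[i]) < 2 * se[i]
    expect_equal(pr$grid$pl[mid],
                 f$logLik - (pr$grid$value[mid] - a[i])^2 / (2 * se[i]^2),
                 tolerance = 1e-4)
    ci <- confidence_interval(pr)
    expect_equal(ci$lower, a[[i]] - qnorm(0.975) * se[i], tolerance = 1e-3)
    expect_equal(ci$upper, a[[i]] + qnorm(0.975) * se[i], tolerance = 1e-3)
    expect_identical(classify_identifiability(pr), "identifiable")
  }
})

test_that("degenerate confidence levels behave at the limits", {
  obj <- quadratic_objective(a = c(x = 1), s = 0.3)
  f <- fit_mle(obj, c(x = 0))
  pr <- profile_likelihood(obj, f, "x", control = fast_profile())
  ci0 <- confidence_interval(pr, alpha = 1e-12)
  expect_equal(ci0$lower, 1, tolerance = 1e-4)
  expect_equal(ci0$upper, 1, tolerance = 1e-4)
})

test_that("a parameter absent from the model has a flat profile", {
  obj <- objective_function(
    fn = function(theta) (theta[1] - 1)^2,
    gr = function(theta) c(2 * (theta[1] - 1), 0),
    lower = c(x = -2, ghost = -2), upper = c(x = 4, ghost = 2))
  f <- fit_mle(obj, c(x = 0, ghost = 0))
  pr <- profile_likelihood(obj, f, "ghost", control = fast_profile())
  expect_identical(classify_identifiability(pr),
                   "structurally_non_identifiable")
  expect_true(pr$hit_lower && pr$hit_upper)
  ci <- confidence_interval(pr)
  expect_true(ci$open_lower && ci$open_upper)
  expect_equal(ci$lower, -2)
  expect_equal(ci$upper, 2)
})

test_that("a one-sided plateau is practically non-identifiable", {
  # saturating response g(t) = t / (1 + t) on the 10^theta scale: the data
  # pin the parameter from below but the likelihood flattens above
  g <- function(theta) {
    u <- 10^theta[1]
    u / (1 + u)
  }
  obj <- objective_function(
    fn = function(theta) 500 * (g(theta) - 0.995)^2,
    lower = c(k = -2), upper = c(k = 3))
  f <- fit_mle(obj, c(k = 0))
  pr <- profile_likelihood(obj, f, "k", control = fast_profile())
  expect_identical(classify_identifiability(pr),
                   "practically_non_identifiable")
  ci <- confidence_interval(pr)
  expect_false(ci$open_lower)
  expect_true(ci$open_upper)
  expect_equal(ci$upper, 3)
})

test_that("non-identifiability counting distinguishes Hill coefficients", {
  # single gene measured only at the mRNA: translation parameters are
  # invisible, so rbs and delta_p have flat profiles
  truth <- single_gene_truth()
  set.seed(43)
  d <- single_gene_data(times = readout_times("ma_high"))
  d <- d[d$species == "mRNA1", ]
  obj <- make_objective(single_gene(), d)
  f <- fit_mle(obj, truth)
  ens <- profile_ensemble(obj, f, control = fast_profile(max_steps = 25))
  expect_gte(count_non_identifiable(ens), 2)
  cls <- vapply(ens$profiles, classify_identifiability, character(1))
  expect_identical(unname(cls["pro_1"]), "identifiable")
  # with protein data as well, everything becomes identifiable
  set.seed(44)
  d2 <- single_gene_data(times = readout_times("ma_high"))
  obj2 <- make_objective(single_gene(), d2)
  f2 <- fit_mle(obj2, truth)
  ens2 <- profile_ensemble(obj2, f2, control = fast_profile())
  expect_identical(count_non_identifiable(ens2), 0L)
  # exclude_hill removes hill-coefficient profiles from the count
  net <- gene_network(c("1", "2"),
    data.frame(from = "1", to = "2", sign = "activation"))
  expect_identical(param_info(net)$type[param_info(net)$name == "h_1_2"],
                   "hill")
})

test_that("the profile-derived parameter set covers the profiles", {
  set.seed(45)
  H <- diag(c(4, 9))
  a <- c(x = 0, y = 1)
  obj <- gaussian_objective(a, H)
  f <- fit_mle(obj, c(x = 0.5, y = 0.5))
  ens <- profile_ensemble(obj, f, control = fast_profile())
  # max_per_profile = 1 keeps only the estimate
  s1 <- profile_parameter_set(ens, max_per_profile = 1)
  expect_identical(nrow(s1), 1L)
  expect_equal(unname(s1[1, ]), unname(f$par), tolerance = 1e-6)
  s10 <- profile_parameter_set(ens, max_per_profile = 10)
  expect_gt(nrow(s10), 10)
  # every member is statistically compatible with the optimum (re-evaluated)
  delta <- qchisq(0.95, 1) / 2
  lls <- -apply(s10, 1, obj$fn)
  expect_true(all(lls >= f$logLik - delta - 1e-6))
  # endpoints of each profile sit at the confidence-interval edges
  se <- sqrt(diag(solve(H)))
  expect_equal(range(s10[, 1]), c(a[[1]] - 1.96 * se[1],
                                  a[[1]] + 1.96 * se[1]), tolerance = 0.05)
})

test_that("confidence-interval coverage is nominal on a small replicate set", {
  truth <- single_gene_truth()
  net <- single_gene()
  times <- readout_times("protein_pair")
  tr <- simulate_grn(net, truth, times)
  x <- pmax(as.vector(tr$states), 0)
  nm <- noise_model()
  set.seed(46)
  hits <- 0
  n <- 40
  for (i in seq_len(n)) {
    y <- simulate_measurement(x, nm)
    d <- grn_dataset("wt", rep(rownames(tr$states), length(times)),
                     rep(times, each = 2), y)
    obj <- make_objective(net, d, noise = nm, clip = TRUE)
    f <- fit_mle(obj, truth)
    ci <- confidence_interval(profile_likelihood(obj, f, "pro_1"))
    hits <- hits + (truth[["pro_1"]] >= ci$lower &&
                    truth[["pro_1"]] <= ci$upper)
  }
  expect_gte(hits / n, 0.8)  # loose screen; the 200-replicate check is in
                             # the acceptance suite
})
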