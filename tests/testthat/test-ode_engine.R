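test_that("integration matches closed forms of the linear single-gene model", {
  net <- single_gene()
  th <- c(pro_1 = 2, rbs_1 = 0.7, delta_p = 0.4)
  times <- c(0, 0.5, 1, 2, 5, 10)
  for (method in c("ros23", "dopri5")) {
    tr <- integrate_ode(build_rhs(net, th), c(mRNA1 = 0, p1 = 0), times,
                        rtol = 1e-9, atol = 1e-12, method = method)
    m_exact <- 2 * (1 - exp(-times))
    expect_equal(unname(tr$states["mRNA1", ]), m_exact, tolerance = 1e-6)
    # protein for time-varying mRNA: p(t) solved exactly for this cascade
    dp <- 0.4
    p_exact <- 0.7 * 2 * ((1 - exp(-dp * times)) / dp -
                          (exp(-dp * times) - exp(-times)) / (1 - dp))
    expect_equal(unname(tr$states["p1", ]), p_exact, tolerance = 1e-6)
  }
})

test_that("protein with constant mRNA follows its closed form", {
  # freeze mRNA at mbar by setting pro = mbar (steady state start)
  net <- single_gene()
  th <- c(pro_1 = 3, rbs_1 = 0.5, delta_p = 0.8)
  times <- c(1, 2, 4, 8)
  tr <- integrate_ode(build_rhs(net, th), c(mRNA1 = 3, p1 = 0), times,
                      rtol = 1e-10, atol = 1e-12)
  p_exact <- (0.5 * 3 / 0.8) * (1 - exp(-0.8 * times))
  expect_equal(unname(tr$states["p1", ]), p_exact, tolerance = 1e-6)
})

test_that("plain-function fallback integrates f == 0 and linear decay", {
  tr <- integrate_ode(function(x) c(0, 0), c(2, 3), c(1, 5, 9))
  expect_true(all(tr$states[1, ] == 2) && all(tr$states[2, ] == 3))
  tr2 <- integrate_ode(function(x) -x, c(a = 1), c(0.5, 1, 2),
                       rtol = 1e-8, atol = 1e-10)
  expect_equal(unname(tr2$states[1, ]), exp(-c(0.5, 1, 2)),
               tolerance = 1e-5)
})

test_that("solver failure is explicit and carries the failing time", {
  net <- single_gene()
  rhs <- build_rhs(net, c(pro_1 = 2, rbs_1 = 1, delta_p = 1))
  err <- tryCatch(
    integrate_ode(rhs, c(mRNA1 = 0, p1 = 0), c(1, 10), maxsteps = 3L,
                  method = "dopri5"),
    grn_integration_error = function(e) e)
  expect_s3_class(err, "grn_integration_error")
  expect_true(is.finite(err$t_fail))
})

test_that("sensitivities match the differentiated closed form", {
  net <- single_gene()
  th_log <- log10(c(pro_1 = 2, rbs_1 = 1, delta_p = 1))
  times <- c(0.5, 1, 3)
  tr <- simulate_grn(net, th_log, times, x0 = c(mRNA1 = 0, p1 = 0),
                     sensitivities = TRUE, rtol = 1e-10, atol = 1e-12)
  # d m(t) / d log10(pro) = ln(10) * pro * (1 - e^-t)
  expect_equal(unname(tr$sens["mRNA1", "pro_1", ]),
               log(10) * 2 * (1 - exp(-times)), tolerance = 1e-5)
  # rbs does not enter the mRNA equation at all
  expect_equal(unname(tr$sens["mRNA1", "rbs_1", ]), rep(0, 3))
  expect_equal(unname(tr$sens["mRNA1", "delta_p", ]), rep(0, 3))
})

test_that("sensitivities agree with finite differences on random networks", {
  set.seed(3)
  for (rep in 1:3) {
    s <- synth_network(3, 3, seed = 300 + rep)
    th <- s$theta_true
    times <- c(1, 4, 12)
    tr <- simulate_grn(s$network, th, times, sensitivities = TRUE,
                       rtol = 1e-10, atol = 1e-12)
    h <- 1e-4
    for (k in seq_along(th)) {
      up <- th; up[k] <- up[k] + h
      dn <- th; dn[k] <- dn[k] - h
      fd <- (simulate_grn(s$network, up, times, rtol = 1e-10,
                          atol = 1e-12)$states -
             simulate_grn(s$network, dn, times, rtol = 1e-10,
                          atol = 1e-12)$states) / (2 * h)
      scale <- max(abs(fd), 1e-4)
      expect_lt(max(abs(tr$sens[, k, ] - fd)) / scale, 1e-3)
    }
  }
})

test_that("halving tolerances moves states by less than the coarse tolerance", {
  # a moderate fixture: steep Hill switches amplify local error into visible
  # global drift, so the check uses tame kinetics (the contract is about
  # tolerance control, not chaos sensitivity)
  net <- synth_network(4, 5, seed = 17)$network
  set.seed(18)
  info <- param_info(net)
  theta <- setNames(ifelse(info$type == "hill", log10(2),
                           runif(nrow(info), -0.5, 0.8)), info$name)
  times <- readout_times("ma_low")
  for (method in c("ros23", "dopri5")) {
    coarse <- simulate_grn(net, theta, times, rtol = 1e-6,
                           atol = 1e-8, method = method)$states
    fine <- simulate_grn(net, theta, times, rtol = 5e-7,
                         atol = 5e-9, method = method)$states
    rel <- max(abs(coarse - fine) / (abs(fine) + 1e-8))
    expect_lt(rel, 1e-4)
  }
})

test_that("the two integration methods agree on a stiff-ish model", {
  s <- synth_network(5, 7, seed = 23)
  th <- s$theta_true
  th["delta_p"] <- 2.5  # fast protein turnover: 10^2.5 per time unit
  times <- readout_times("ma_low")
  a <- simulate_grn(s$network, th, times, rtol = 1e-8, atol = 1e-10,
                    method = "ros23")$states
  b <- simulate_grn(s$network, th, times, rtol = 1e-8, atol = 1e-10,
                    method = "dopri5")$states
  expect_lt(max(abs(a - b) / (abs(b) + 1e-6)), 1e-3)
})

test_that("trajectory conversion and CSV dump keep the long format", {
  net <- single_gene()
  tr <- simulate_grn(net, single_gene_truth(), c(1, 2))
  df <- as.data.frame(tr)
  expect_identical(names(df), c("species", "time", "value"))
  expect_identical(nrow(df), 4L)
  path <- tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  expect_equal(read.csv(path)$value, df$value)
})
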