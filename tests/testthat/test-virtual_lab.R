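test_that("the generated truth is reproducible and well-formed", {
  s1 <- synth_network(6, 8, seed = 61)
  s2 <- synth_network(6, 8, seed = 61)
  expect_identical(s1$network$interactions, s2$network$interactions)
  expect_identical(s1$theta_true, s2$theta_true)
  expect_identical(count_parameters(s1$network), 29L)
  # Hill truths are integers 1..8 on the linear scale
  info <- param_info(s1$network)
  hills <- 10^s1$theta_true[info$name[info$type == "hill"]]
  expect_equal(hills, round(hills), tolerance = 1e-9)
  expect_true(all(round(hills) %in% 1:8))
  others <- s1$theta_true[info$type != "hill"]
  expect_true(all(others >= -2 & others <= 3))
  # a single constitutive gene
  s3 <- synth_network(1, 0, seed = 62)
  expect_identical(nrow(s3$network$interactions), 0L)
  expect_error(synth_network(3, 7), "G\\*\\(G-1\\)")
})

test_that("budget ledger reproduces the challenge arithmetic", {
  s <- synth_network(6, 8, seed = 63)
  state <- challenge_init(s$network, s$theta_true, seed = 63)
  expect_equal(state$budget, 10000)
  designs <- enumerate_designs(s$network)
  # buy wildtype protein data for all six proteins: three pair purchases
  pairs <- designs[designs$pert_kind == "wildtype" &
                   designs$readout_type == "protein_pair", ]
  for (pick in c("wt:protein_pair_p1_p2", "wt:protein_pair_p3_p4",
                 "wt:protein_pair_p5_p6"))
    state <- purchase(state, pairs[pairs$id == pick, ])
  expect_equal(state$budget, 8800)
  # then the wildtype high-density microarray
  state <- purchase(state, "wt:ma_high")
  expect_equal(state$budget, 7800)
  # ledger replay: remaining = initial - cumulative costs, always
  expect_equal(state$ledger$remaining,
               10000 - cumsum(state$ledger$cost))
  # refusal with shortfall
  state$budget <- 50
  gs <- designs[designs$readout_type == "gelshift", ][1, ]
  err <- tryCatch(purchase(state, gs),
                  grn_insufficient_credits = function(e) e)
  expect_s3_class(err, "grn_insufficient_credits")
  expect_equal(err$shortfall, 1550)
})

test_that("purchased data are deterministic given seed and ledger", {
  s <- synth_network(3, 3, seed = 64)
  st1 <- challenge_init(s$network, s$theta_true, seed = 7)
  st2 <- challenge_init(s$network, s$theta_true, seed = 7)
  expect_identical(st1$data, st2$data)
  st1 <- purchase(st1, "sirna_2:protein_pair_p1_p3")
  st2 <- purchase(st2, "sirna_2:protein_pair_p1_p3")
  expect_identical(st1$data, st2$data)
  # a different lab seed vends different noise
  st3 <- challenge_init(s$network, s$theta_true, seed = 8)
  expect_false(identical(st1$data$value, st3$data$value))
  # purchases register their condition for later fitting
  expect_true("sirna_2" %in% names(st1$conditions))
  expect_identical(st1$conditions$sirna_2$kind, "sirna")
})

test_that("gel-shift purchases return the exact interaction parameters", {
  s <- synth_network(3, 3, seed = 65)
  state <- challenge_init(s$network, s$theta_true, seed = 65)
  ia <- s$network$interactions[2, ]
  id <- paste0("gelshift_", ia$from, "_", ia$to)
  state <- purchase(state, id)
  pn <- paste0(c("h_", "Kd_"), ia$from, "_", ia$to)
  expect_identical(state$known_params[pn], s$theta_true[pn])
  expect_equal(state$budget, 10000 - 1600)
})

test_that("data-points-per-credit ratios match the published arithmetic", {
  net <- example_network("model_a")
  expect_equal(data_points_per_credit("protein_pair", net), 0.2)
  expect_equal(data_points_per_credit("ma_high", net), 120 / 1000)
  g9 <- example_network("model_c")
  expect_equal(data_points_per_credit("ma_high", g9), 180 / 1000)
  broken <- cost_table()
  broken$readout[["protein_pair"]] <- 0  # zero-cost hypothetical
  expect_error(data_points_per_credit("protein_pair", net, broken),
               "positive")
})

test_that("parameter distance is the summed squared log10 deviation", {
  th <- c(a = 0.5, b = 1, c = -1)
  expect_equal(param_distance(th, th), 0)
  off <- th; off["b"] <- th["b"] + 1  # one parameter off by a factor of 10
  expect_equal(param_distance(off, th), 1)
  expect_equal(param_distance(off, th, mode = "absolute"), 1)
  off2 <- th + c(0.1, -0.2, 0.3)
  expect_equal(param_distance(off2, th), sum(c(0.1, 0.2, 0.3)^2))
  expect_error(param_distance(c(a = 1), th), "align")
  md <- mean_deviation(off, th)
  expect_equal(unname(md["mean_abs_log10"]), 1 / 3)
})

test_that("cost table round-trips through JSON", {
  ct <- cost_table(ma_low = 700, knockout = 500, initial_budget = 9000)
  path <- tempfile(fileext = ".json")
  write_cost_table(ct, path)
  ct2 <- read_cost_table(path)
  expect_equal(ct2$readout, ct$readout)
  expect_equal(ct2$surcharge, ct$surcharge)
  expect_equal(ct2$initial_budget, 9000)
})

test_that("a tiny benchmark loop runs, spends within budget, deterministically", {
  ctrl <- fast_profile(max_steps = 3, target_frac = 0.5)
  b1 <- run_benchmark_loop(3, 3, seed = 66, strategy = "cheapest",
                           budget = 1200, max_steps = 2, n_starts = 2,
                           track_identifiability = FALSE)
  expect_true(all(b1$remaining >= 0))
  expect_identical(tail(b1$action, 1), "final")
  expect_true(all(diff(b1$remaining) <= 0))
  b2 <- run_benchmark_loop(3, 3, seed = 66, strategy = "cheapest",
                           budget = 1200, max_steps = 2, n_starts = 2,
                           track_identifiability = FALSE)
  expect_identical(b1$distance, b2$distance)  # fixed given a seed
  # cheapest always buys the cheapest affordable design
  costs <- cost_table()
  expect_identical(b1$cost[1],
                   min(enumerate_designs(attr(b1, "state")$network)$cost))
  b3 <- run_benchmark_loop(3, 3, seed = 67, strategy = "random",
                           budget = 1200, max_steps = 1, n_starts = 2,
                           track_identifiability = FALSE)
  expect_true(all(b3$remaining >= 0))
})
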