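test_that("the design space has (3G+1)(choose(G,2)+2)+I members", {
  expect_identical(nrow(enumerate_designs(example_network("model_a"))), 331L)
  expect_identical(nrow(enumerate_designs(example_network("model_b"))), 516L)
  expect_identical(nrow(enumerate_designs(example_network("model_c"))), 1079L)
  # 2 genes, no interactions: 7 conditions x (1 pair + 2 microarrays)
  net2 <- gene_network(c("1", "2"))
  expect_identical(nrow(enumerate_designs(net2)), 21L)
  # formula vs brute-force construction on random networks
  set.seed(50)
  for (rep in 1:5) {
    G <- sample(2:7, 1)
    I <- sample(0:min(12, (G - 1)^2), 1)
    net <- synth_network(G, I, seed = 500 + rep)$network
    d <- enumerate_designs(net)
    expect_equal(nrow(d), (3 * G + 1) * (choose(G, 2) + 2) + I)
    expect_false(anyDuplicated(d$id) > 0)
    # protein pairs unordered and distinct
    pp <- d[d$readout_type == "protein_pair", ]
    expect_true(all(pp$readout_a != pp$readout_b))
  }
})

test_that("design costs are readout price plus perturbation surcharge", {
  d <- enumerate_designs(example_network("model_a"))
  expect_equal(unique(d$cost[d$pert_kind == "wildtype" &
                             d$readout_type == "protein_pair"]), 400)
  expect_equal(unique(d$cost[d$pert_kind == "sirna" &
                             d$readout_type == "protein_pair"]), 750)
  expect_equal(unique(d$cost[d$pert_kind == "rbs_boost" &
                             d$readout_type == "protein_pair"]), 850)
  expect_equal(unique(d$cost[d$readout_type == "gelshift"]), 1600)
  expect_equal(unique(d$cost[d$pert_kind == "wildtype" &
                             d$readout_type == "ma_high"]), 1000)
})

test_that("predict_readout honours the perturbation and the readout grid", {
  s <- synth_network(3, 2, seed = 51)
  d <- enumerate_designs(s$network)
  wt_ma <- d[d$id == "wt:ma_high", ]
  tr <- predict_readout(s$network, s$theta_true, wt_ma)
  ref <- simulate_grn(s$network, s$theta_true, readout_times("ma_high"),
                      rtol = 1e-7, atol = 1e-9)
  expect_equal(tr$states, ref$states[paste0("mRNA", s$network$genes), ])
  # knockout readouts decay towards zero at late times
  ko <- d[d$pert_kind == "knockout" & d$pert_gene == "1" &
          d$readout_type == "ma_high", ]
  trko <- predict_readout(s$network, s$theta_true, ko)
  expect_lt(trko$states["mRNA1", ncol(trko$states)], 1e-6)
  expect_error(predict_readout(s$network, s$theta_true,
                               d[d$readout_type == "gelshift", ][1, ]),
               "gel-shift")
})

test_that("the spread score matches the hand-computed oracle", {
  nm <- noise_model(sigma_abs = 0.1, sigma_rel = 0.2)
  # two constant trajectories at 0 and 1; sigma from the estimate's
  # trajectory (constant 1): R = (1 - 0) / sqrt(0.1^2 + 0.2^2)
  arr <- array(rep(c(0, 1), each = 4), dim = c(1, 4, 2))
  hat <- matrix(1, 1, 4)
  sc <- grndesign:::spread_score(arr, hat, nm)
  expect_equal(unique(as.vector(sc)), 1 / sqrt(0.05))
  expect_equal(1 / sqrt(0.05), 4.47214, tolerance = 1e-5)
  # identical trajectories score zero
  arr0 <- array(rep(2, 8), dim = c(1, 4, 2))
  expect_true(all(grndesign:::spread_score(arr0, hat, nm) == 0))
})

test_that("design scores are permutation-invariant and flag gel-shifts", {
  s <- synth_network(3, 2, seed = 52)
  designs <- enumerate_designs(s$network)
  stilde <- rbind(s$theta_true, s$theta_true + 0.15, s$theta_true - 0.1)
  sc1 <- score_designs(s$network, stilde, designs,
                       theta_hat = s$theta_true)
  sc2 <- score_designs(s$network, stilde[c(3, 1, 2), ], designs,
                       theta_hat = s$theta_true)
  expect_equal(sc1$R, sc2$R, tolerance = 1e-12)
  expect_true(all(sc1$R >= 0))
  # identical vectors: all time-course scores collapse to zero
  sc0 <- score_designs(s$network, rbind(s$theta_true, s$theta_true),
                       designs, theta_hat = s$theta_true)
  expect_true(all(sc0$R[sc0$readout_type != "gelshift"] == 0))
  # gel-shift scoring keys on non-identifiable parameters
  ia <- s$network$interactions[1, ]
  hname <- paste0("h_", ia$from, "_", ia$to)
  scg <- score_designs(s$network, stilde, designs,
                       theta_hat = s$theta_true, nonid_params = hname)
  gs <- scg[scg$readout_type == "gelshift", ]
  expect_true(is.infinite(gs$R[gs$interaction == 1]))
  expect_true(all(gs$R[gs$interaction != 1] == 0))
})

test_that("ranking is score-descending with cheapness as tie-breaker", {
  sc <- data.frame(id = c("a", "b", "c", "d"),
                   R = c(10, 9.5, 5, 4),
                   cost = c(1000, 750, 400, 10000))
  rk <- rank_designs(sc, budget = 2000)
  # a and b tie within 10%: cheaper b first
  expect_identical(rk$recommended$id[1:2], c("b", "a"))
  expect_identical(rk$recommended$id[3], "c")
  expect_identical(rk$excluded$id, "d")
  # single affordable design
  rk2 <- rank_designs(sc, budget = 500)
  expect_identical(rk2$recommended$id, "c")
  # nothing affordable: empty recommendation, full excluded list
  rk3 <- rank_designs(sc, budget = 100)
  expect_identical(nrow(rk3$recommended), 0L)
  expect_identical(nrow(rk3$excluded), 4L)
})

test_that("extrapolation spread is zero for parameters outside the readout", {
  # two unconnected genes with the shared protein degradation rate held
  # fixed: gene 1's translation strength then cannot influence p2 even
  # through companion re-optimization, while pro_2 feeds p2 directly
  net <- gene_network(c("1", "2"))
  truth <- setNames(c(0.3, 0.5, -0.2, 0.1, -0.3), param_info(net)$name)
  set.seed(53)
  d <- wt_data(net, truth)  # all species: every parameter pinned
  obj <- make_objective(net, d)
  fixed <- truth["delta_p"]
  f <- fit_mle(obj, truth, fixed = fixed)
  ens <- profile_ensemble(obj, f, params = c("rbs_1", "pro_2"),
                          fixed = fixed, control = fast_profile())
  eu <- extrapolation_uncertainty(net, ens, perturbation("sirna", "1"),
                                  species = "p2",
                                  times = c(5, 10, 20))
  s_rbs1 <- eu$spread[eu$parameter == "rbs_1"]
  s_pro2 <- eu$spread[eu$parameter == "pro_2"]
  expect_lt(s_rbs1, 1e-3)
  expect_gt(s_pro2, 10 * max(s_rbs1, 1e-12))
  expect_identical(eu$parameter[1], "pro_2")
})

test_that("a design step reports scores and knows when to stop", {
  truth <- single_gene_truth()
  set.seed(54)
  d <- single_gene_data()
  rep1 <- design_step(single_gene(), d, list(wt = perturbation("wildtype")),
                      budget = 5000, n_starts = 2, seed = 55,
                      control = fast_profile())
  # every affordable design is listed with a score and its cost
  aff <- rep1$ranking$recommended
  all_d <- enumerate_designs(single_gene())
  expect_setequal(aff$id, all_d$id[all_d$cost <= 5000])
  expect_true(all(is.finite(aff$R) | aff$R == Inf))
  expect_output(print(rep1), "budget")
  # the single-gene model with rich two-species data is fully identified:
  # recommend stopping
  if (rep1$nonid_count == 0 && max(aff$R[is.finite(aff$R)]) < 1)
    expect_true(rep1$stop_recommended)
})
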