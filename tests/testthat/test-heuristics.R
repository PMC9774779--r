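test_that("parallel selection ratios follow the pooled arithmetic", {
  # constructed tie: (109 + 1) / (60 + 50) = 1
  g <- growth_numbers(109, 80, 60, 50)
  expect_equal(unname(parallel_ratios(g)["A"]), 1)
  # equal per-host growth: the generalist's arithmetic advantage
  g2 <- growth_numbers(100, 100, 100, 100)
  expect_equal(unname(parallel_ratios(g2)), c(0.505, 0.505))
  # ratios equal pooled descendants of specialist over generalist
  pooled_spec_A <- g2["phiA", "A"] + 1
  pooled_gen <- g2["phiAB", "A"] + g2["phiAB", "B"]
  expect_equal(unname(parallel_ratios(g2)["A"]), pooled_spec_A / pooled_gen)
  expect_error(parallel_ratios(growth_numbers(10, 10, 0, 0)), "undefined")
})

test_that("sequential selection ratios are multiplicative", {
  g <- growth_numbers(100, 100, 10, 10)
  expect_equal(unname(sequential_ratios(g)["A"]), 1)
  g2 <- growth_numbers(100, 80, 60, 50)
  expect_equal(unname(sequential_ratios(g2)["A"]), 100 / 3000)
})

test_that("sequential never favors the specialist more than parallel once the generalist grows at least twofold per host", {
  # product >= sum requires both generalist growth numbers >= 2
  # (xy >= x + y iff 1/x + 1/y <= 1); below that the ordering can flip
  spec_vals <- 10^seq(log10(1.1), 6, length.out = 6)
  gen_vals <- 10^seq(log10(2), 6, length.out = 6)
  for (nA in spec_vals) for (nGA in gen_vals) for (nGB in gen_vals) {
    g <- growth_numbers(nA, 1.5, nGA, nGB)
    expect_lte(sequential_ratios(g)[["A"]], parallel_ratios(g)[["A"]])
  }
  # the flip at the low corner: weak generalist growth on both hosts
  weak <- growth_numbers(100, 1.5, 1.1, 1.1)
  expect_gt(sequential_ratios(weak)[["A"]], parallel_ratios(weak)[["A"]])
})

test_that("ratio scaling algebra: the +1 survival term breaks homogeneity", {
  g <- growth_numbers(120, 40, 70, 30)
  for (c in c(0.5, 2, 10)) {
    gc <- growth_numbers(120 * c, 40 * c, 70 * c, 30 * c)
    # parallel: (cN + 1) / (c (N' + N'')) -- not scale invariant
    expect_equal(unname(parallel_ratios(gc)["A"]),
                 (120 * c + 1) / (c * (70 + 30)))
    # sequential scales exactly as 1/c
    expect_equal(unname(sequential_ratios(gc)),
                 unname(sequential_ratios(g)) / c)
  }
})

test_that("heuristic classification encodes the generalist's asymmetry", {
  # specialist ratio < 1 predicts that specialist lost
  lostA <- growth_numbers(50, 500, 100, 100)
  expect_equal(unname(heuristic_outcome(lostA, "parallel")),
               c("lost", "retained", "retained"))
  # one specialist beating the generalist does not force generalist loss
  oneup <- growth_numbers(500, 50, 100, 100)
  expect_equal(unname(heuristic_outcome(oneup, "parallel")["phiAB"]),
               "retained")
  # both specialists ahead: generalist predicted lost
  both <- growth_numbers(500, 500, 100, 100)
  expect_equal(unname(heuristic_outcome(both, "parallel")["phiAB"]), "lost")
})

test_that("the tyranny diagnostic flags per-host winners that lose overall", {
  # B-specialist wins host B (8 > 4) yet the generalist's output on the
  # productive host A swamps the pool
  g <- growth_numbers(1000, 8, 900, 4)
  rep <- generalist_tyranny(g)
  expect_identical(unname(rep$per_host_winner["B"]), "phiB")
  expect_true(rep$tyranny[["phiB"]])
  expect_false(rep$tyranny[["phiA"]])
  # no tyranny when each host's winner also wins the pool
  g2 <- growth_numbers(100, 100, 50, 50)
  expect_false(any(generalist_tyranny(g2)$tyranny))
})

test_that("measured growth numbers recover the per-culture ratios", {
  cfg <- quick_config(n_cycles = 2)
  run <- run_protocol(cfg, asym_params())
  g <- measure_growth_numbers(run, 0)
  # non-permissive entries sit at the survival value 1 (inert dynamics)
  expect_equal(g["phiA", "B"], 1)
  expect_equal(g["phiB", "A"], 1)
  # permissive entries match the recorded per-culture end/start directly
  d <- run$culture_detail[[1]]
  expect_equal(g["phiA", "A"],
               d$end_by_culture$A[["phiA"]] / d$start[["phiA"]])
  expect_equal(g["phiAB", "B"],
               d$end_by_culture$B[["phiAB"]] / d$start[["phiAB"]])
  # mixed cultures cannot attribute generalist growth per host
  mrun <- run_protocol(quick_config("mixed", n_cycles = 1), asym_params())
  expect_error(measure_growth_numbers(mrun, 0), "mixed")
})

test_that("measured ratios predict short head-to-head outcomes", {
  cfg <- quick_config(n_cycles = 2)
  for (gen in list(c(25, 25), c(5, 5))) {
    run <- run_protocol(cfg, asym_params(gen = gen))
    r <- parallel_ratios(measure_growth_numbers(run, 0))
    # frequency trajectory of the A-specialist relative to the generalist
    f1 <- run$cycles$end_phiA[1] / run$cycles$end_phiAB[1]
    f2 <- run$cycles$end_phiA[2] / run$cycles$end_phiAB[2]
    if (r[["A"]] > 1) expect_gt(f2, f1) else expect_lt(f2, f1)
  }
})

test_that("bottleneck survival multiplies transfer and placement odds", {
  expect_equal(bottleneck_survival(10, 10, 4, 4), 1)
  expect_equal(bottleneck_survival(37, 4.5, 8, 2), 4.5 / 37 * 2 / 8)
  expect_equal(bottleneck_survival(2, 1, 10, 1), 0.05)
  expect_error(bottleneck_survival(10, 11, 4, 2))
  expect_error(bottleneck_survival(10, 5, 4, 5))
  # monotone nondecreasing in volumes used and useful cultures
  base <- bottleneck_survival(37, 4.5, 8, 2)
  expect_gte(bottleneck_survival(37, 9, 8, 2), base)
  expect_gte(bottleneck_survival(37, 4.5, 8, 4), base)
})
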