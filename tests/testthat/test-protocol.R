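test_that("cycle cultures follow the presentation mode", {
  inc <- c(phiA = 333.3, phiB = 333.3, phiAB = 333.3)
  par <- quick_config("parallel")
  cs <- build_cycle_cultures(par, 0, inc)
  expect_length(cs, 2)
  expect_equal(cs$A$cells[["A"]], 1e7)
  expect_equal(cs$A$cells[["B"]], 0)
  expect_equal(cs$B$cells[["B"]], 1e7)
  expect_equal(unname(cs$A$free_phage), unname(inc))
  expect_equal(unname(cs$B$free_phage), unname(inc))

  seqc <- quick_config("sequential")
  hosts <- vapply(0:2, function(i) {
    names(build_cycle_cultures(seqc, i, inc))
  }, character(1))
  expect_identical(hosts, c("A", "B", "A"))

  mix <- quick_config("mixed")
  cm <- build_cycle_cultures(mix, 0, inc)
  expect_length(cm, 1)
  expect_equal(unname(cm$AB$cells), c(1e7, 1e7))
})

test_that("pooling sums equal-volume densities and drops infected by default", {
  a <- culture_state(free_phage = c(phiA = 2e8), cells = c(A = 1e7))
  b <- culture_state(free_phage = c(phiA = 1000), cells = c(B = 1e7))
  pool <- pool_cultures(list(a, b))
  expect_equal(pool$free_phage[["phiA"]], 2.00001e8)
  expect_null(pool$infected)
  expect_equal(pool_cultures(list(a))$free_phage, a$free_phage)
  expect_error(pool_cultures(list()), "no cultures")
  # specialist pooled growth is N + 1: growth 100x on A, survival on B
  start <- c(phiA = 1000, phiB = 0, phiAB = 0)
  endA <- culture_state(free_phage = c(phiA = 1e5), cells = c(A = 1))
  endB <- culture_state(free_phage = c(phiA = 1000), cells = c(B = 1))
  pooled <- pool_cultures(list(endA, endB))$free_phage
  expect_equal(pooled[["phiA"]] / start[["phiA"]], 101)
})

test_that("dilution modes rescale as specified", {
  cfg <- quick_config("parallel", "fixed_count")
  pool <- c(phiA = 800, phiB = 150, phiAB = 50)
  out <- apply_dilution(pool, cfg)
  expect_equal(out$phage, pool)  # already at the 1000 target
  big <- pool * 1250  # total 1.25e6
  out2 <- apply_dilution(big, cfg)
  expect_equal(sum(out2$phage), 1000, tolerance = 1e-12)
  # proportions preserved exactly
  expect_equal(out2$phage / sum(out2$phage), big / sum(big))
  expect_equal(apply_dilution(c(phiA = 1e6, phiB = 0, phiAB = 0),
                              cfg)$factor, 1e-3)

  cfgv <- quick_config("parallel", "fixed_volume")
  outv <- apply_dilution(c(phiA = 1e6, phiB = 0, phiAB = 0), cfgv)
  expect_equal(sum(outv$phage), 5e4)

  # per-host rescaling: each culture normalized to 1000 before combining
  cfgh <- quick_config("parallel", "fixed_count_by_host")
  per <- list(A = c(phiA = 2e6, phiB = 0, phiAB = 2e6),
              B = c(phiA = 0, phiB = 10, phiAB = 990))
  outh <- apply_dilution(per$A + per$B, cfgh, per)
  expect_equal(sum(outh$phage), 2000)
  expect_equal(outh$phage[["phiB"]], 10)
  expect_error(apply_dilution(per$A, cfgh), "per_culture_pools")

  # empty pool flags extinction instead of dividing by zero
  oute <- apply_dilution(c(phiA = 0, phiB = 0, phiAB = 0), cfg)
  expect_true(oute$extinct)
  expect_true(all(oute$phage == 0))
})

test_that("config validation catches inconsistent protocols", {
  expect_error(protocol_config("sequential", "fixed_count_by_host"),
               "parallel")
  expect_error(protocol_config(cycle_length = 0), "cycle_length")
  expect_error(protocol_config(transfer_fraction = 1.5), "transfer_fraction")
})

test_that("a run conserves frequency bookkeeping", {
  run <- run_protocol(quick_config(n_cycles = 4), asym_params())
  expect_equal(sum(run$final_frequencies), 1)
  expect_true(all(run$final_frequencies >= 0))
  expect_equal(nrow(run$cycles), 4)
  expect_identical(run$cycles$cycle_index, 0:3)
  # every recorded density non-negative
  num <- vapply(run$cycles, is.numeric, logical(1))
  expect_true(all(as.matrix(run$cycles[num]) >= 0, na.rm = TRUE))
})

test_that("symmetric specialists without a generalist split the pool evenly", {
  p <- kinetic_params(burst_A = 15, burst_B = 15, burst_AB = 0, r = 0.3)
  run <- run_protocol(quick_config(n_cycles = 6), p)
  expect_lt(rel_diff(run$final_frequencies[["phiA"]],
                     run$final_frequencies[["phiB"]]), 1e-9)
})

test_that("fold growth settles at 1/transfer_fraction under fixed volume", {
  cfg <- protocol_config("parallel", "fixed_volume", n_cycles = 40)
  run <- run_protocol(cfg, asym_params(r = 0.1))
  expect_equal(fold_growth(run, 39), 1 / cfg$transfer_fraction,
               tolerance = 0.01)
  expect_equal(fold_growth(run, 0),
               run$cycles$fold_growth[1])
})

test_that("retention under the canonical short-term dynamics conditions", {
  # low bacterial growth + fixed count: only the A-specialist survives
  low <- run_protocol(protocol_config("parallel", "fixed_count"),
                      asym_params(r = 0.1))
  expect_equal(unname(classify_retention(low$final_frequencies)),
               c("retained", "lost", "lost"))
  expect_gt(low$final_frequencies[["phiA"]], 0.99)
  # raising r to 0.3 restores the generalist alongside the A-specialist
  high <- run_protocol(protocol_config("parallel", "fixed_count"),
                       asym_params(r = 0.3))
  expect_equal(unname(classify_retention(high$final_frequencies)),
               c("retained", "lost", "retained"))
})

test_that("run output methods expose the per-cycle records", {
  run <- run_protocol(quick_config(n_cycles = 3), asym_params(),
                      record_trajectories = TRUE)
  expect_s3_class(as.data.frame(run), "data.frame")
  expect_output(print(run), "final frequencies")
  expect_output(print(summary(run)), "retention")
  tf <- phagetrain:::trajectory_frame(run)
  expect_true(all(c("time", "culture_id") %in% names(tf)))
  expect_equal(max(tf$time), 60)  # 3 cycles x 20 units
})
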