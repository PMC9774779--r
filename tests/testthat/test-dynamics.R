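test_that("derivatives reduce to the expected closed forms in limits", {
  p <- kinetic_params(burst_A = 20, r = 0.1)
  # no phage at all: pure exponential cell growth
  s <- culture_state(cells = c(A = 1e7))
  d <- phage_derivatives(s, p)
  expect_equal(unname(d$cells["A"]), 1e6)
  expect_true(all(d$free_phage == 0) && all(d$infected == 0))
  # specialist on its non-permissive host: fully inert
  s2 <- culture_state(free_phage = c(phiA = 1000), cells = c(B = 1e7))
  p2 <- kinetic_params(burst_A = 20, burst_B = 10, r = 0.1)
  d2 <- phage_derivatives(s2, p2)
  expect_identical(unname(d2$free_phage["phiA"]), 0)
  expect_identical(unname(d2$infected["phiA", "B"]), 0)
})

test_that("derivatives evaluate the infection model term by term", {
  p <- kinetic_params(burst_A = 20, r = 0.3)
  s <- culture_state(free_phage = c(phiA = 1000), cells = c(A = 1e7))
  d <- phage_derivatives(s, p)
  # k P C = 1e-9 * 1e3 * 1e7 = 10
  expect_equal(unname(d$free_phage["phiA"]), -10)
  expect_equal(unname(d$infected["phiA", "A"]), 10)
  expect_equal(unname(d$cells["A"]), 3e6 - 10)
})

test_that("free-phage adsorption loss equals infected gain, pair by pair", {
  p <- asym_params()
  set.seed(7)
  for (rep in 1:10) {
    P <- setNames(10^runif(3, 0, 8), c("phiA", "phiB", "phiAB"))
    C <- setNames(10^runif(2, 3, 9), c("A", "B"))
    Im <- matrix(10^runif(6, 0, 5), 3, 2) * strain_set()$permissivity
    s <- culture_state(free_phage = P, cells = C, infected = Im)
    d <- phage_derivatives(s, p)
    ads <- p$adsorption * outer(P, C)  # the only P -> I flux
    # dI restores exactly ads - lysis; dP's loss is exactly rowSums(ads)
    expect_equal(d$infected, ads - p$lysis * Im)
    expect_equal(unname(d$free_phage),
                 unname(rowSums(p$burst * p$lysis * Im) - rowSums(ads)))
  }
})

test_that("integration reproduces closed forms in phage-free and inert limits", {
  p <- kinetic_params(burst_A = 20, r = 0.1)
  s <- culture_state(cells = c(A = 1e7))
  exact <- 1e7 * exp(0.1 * 20)
  eu <- integrate_culture(s, p, 20, solver = "euler")$final
  ad <- integrate_culture(s, p, 20, solver = "adaptive")$final
  expect_lt(rel_diff(eu$cells[["A"]], exact), 1e-3)
  expect_lt(rel_diff(ad$cells[["A"]], exact), 1e-6)
  # inert phage density is constant to machine precision
  s2 <- culture_state(free_phage = c(phiA = 1000), cells = c(B = 1e7))
  p2 <- kinetic_params(burst_A = 20, burst_B = 10, r = 0.1)
  eu2 <- integrate_culture(s2, p2, 20, solver = "euler")$final
  expect_identical(eu2$free_phage[["phiA"]], 1000)
})

test_that("Euler and the adaptive reference agree at endpoints within 1%", {
  for (nm in c("fig2", "fig3", "fig4", "fig6")) {
    fx <- scenario_fixture(nm)
    par <- set_generalist_burst(fx$params, 17, 17)
    s <- culture_state(free_phage = c(phiA = 333, phiB = 333, phiAB = 334),
                       cells = c(A = 1e7))
    eu <- integrate_culture(s, par, 20, solver = "euler")$final
    ad <- integrate_culture(s, par, 20, solver = "adaptive")$final
    keep <- eu$free_phage > 1  # ignore empty compartments
    expect_lt(max(rel_diff(eu$free_phage[keep], ad$free_phage[keep])), 0.01)
    # cells: relative agreement while populated, both exhausted otherwise
    if (sum(ad$cells) > 1) {
      expect_lt(rel_diff(sum(eu$cells), sum(ad$cells)), 0.01)
    } else {
      expect_lt(sum(eu$cells), 1)
    }
  }
})

test_that("trajectories sample every unit time and stay non-negative", {
  p <- asym_params()
  s <- culture_state(free_phage = c(phiA = 333, phiB = 333, phiAB = 334),
                     cells = c(A = 1e7))
  tr <- integrate_culture(s, p, 20)
  expect_true(all(0:20 %in% round(tr$times, 6)))
  expect_true(all(tr$states >= 0))
})

test_that("invasion rate is the dominant eigenvalue of the excess-cell limit", {
  p <- kinetic_params(burst_A = 1)
  expect_equal(invasion_rate(p, "phiA", "A", 1e7), 0)
  p20 <- kinetic_params(burst_A = 20)
  # positive root of s^2 + 1.01 s - 0.19 = 0
  expect_equal(invasion_rate(p20, "phiA", "A", 1e7),
               (-1.01 + sqrt(1.01^2 + 4 * 0.19)) / 2)
  expect_equal(invasion_rate(p20, "phiA", "A", 1e7), 0.1621019,
               tolerance = 1e-6)
  expect_error(invasion_rate(p20, "phiA", "B", 1e7), "permissive")
  # simulated early log-slope of P + I in effectively constant cells
  pc <- kinetic_params(burst_A = 20, r = 0)
  s <- culture_state(free_phage = c(phiA = 1), cells = c(A = 1e7))
  df <- as.data.frame(integrate_culture(s, pc, 10, solver = "adaptive"))
  tot <- df$P_phiA + df$I_phiA_A
  slope <- unname(coef(lm(log(tot[6:11]) ~ df$time[6:11]))[2])
  expect_lt(abs(slope / invasion_rate(pc, "phiA", "A", 1e7) - 1), 0.02)
})

test_that("the integrator reports blow-ups instead of returning garbage", {
  p <- asym_params()
  s <- culture_state(free_phage = c(phiA = 1e9), cells = c(A = 1e9))
  # absurdly large step makes Euler undershoot far below zero
  expect_error(integrate_culture(s, p, 20, step = 5), "negative|non-finite")
})
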