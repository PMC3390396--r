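test_that("class I simulator validates parameters and handles edge cases", {
  expect_error(simulate_class1_positions(nu = 0.5, mu = 1), "nu")
  expect_error(simulate_class1_positions(nu = Inf, mu = 1), "nu")
  expect_error(simulate_class1_positions(nu = 2, mu = -1), "mu")
  expect_error(simulate_class1_positions(nu = 2, mu = 1, length = 0), "length")
  expect_identical(simulate_class1_positions(nu = 8.39, mu = 0), numeric(0))
})

test_that("class I positions are sorted and strictly inside the interval", {
  set.seed(11)
  for (i in 1:50) {
    p <- simulate_class1_positions(nu = 8.39, mu = 3, length = 0.8)
    expect_true(all(diff(p) > 0))
    expect_true(all(p > 0 & p < 0.8))
  }
})

test_that("expected event count is mu * length for both pathway simulators", {
  set.seed(21)
  n <- 10000
  c1 <- replicate(n, length(simulate_class1_positions(8.39, mu = 2, length = 1)))
  se1 <- sd(c1) / sqrt(n)
  expect_lt(abs(mean(c1) - 2), 3 * se1)
  c2 <- replicate(n, length(simulate_class2_positions(rate = 2, length = 1)))
  se2 <- sd(c2) / sqrt(n)
  expect_lt(abs(mean(c2) - 2), 3 * se2)
})

test_that("gap CV matches the closed form 1/sqrt(nu)", {
  set.seed(31)
  # one long interval pools many gaps; interior gaps of the stationary
  # process are exactly Gamma(nu, mean 1/mu), so CV = 1/sqrt(nu)
  p <- simulate_class1_positions(nu = 8.39, mu = 2, length = 5000)
  gaps <- diff(p)
  expect_gt(length(gaps), 5000)
  expect_equal(sd(gaps) / mean(gaps), 1 / sqrt(8.39), tolerance = 0.03)
})

test_that("interior gaps follow Gamma(nu, rate = nu * mu) by KS", {
  set.seed(41)
  p <- simulate_class1_positions(nu = 4, mu = 2, length = 5000)
  ks <- stats::ks.test(diff(p), "pgamma", shape = 4, rate = 8)
  expect_gt(ks$p.value, 0.01)
  # ordinary (non-equilibrium) start: interior gaps are still gamma
  p2 <- simulate_class1_positions(nu = 4, mu = 2, length = 5000,
                                  start = "ordinary")
  ks2 <- stats::ks.test(diff(p2), "pgamma", shape = 4, rate = 8)
  expect_gt(ks2$p.value, 0.01)
})

test_that("with nu = 1 class I and class II simulators are indistinguishable", {
  set.seed(51)
  n <- 3000
  n1 <- replicate(n, length(simulate_class1_positions(1, mu = 3, length = 1)))
  n2 <- replicate(n, length(simulate_class2_positions(rate = 3, length = 1)))
  expect_gt(suppressWarnings(stats::ks.test(n1, n2))$p.value, 0.01)
  g1 <- diff(simulate_class1_positions(1, mu = 3, length = 2000))
  g2 <- diff(simulate_class2_positions(rate = 3, length = 2000))
  expect_gt(suppressWarnings(stats::ks.test(g1, g2))$p.value, 0.01)
})

test_that("class II counts pass a Poisson GOF under the null", {
  set.seed(61)
  counts <- replicate(2000, length(simulate_class2_positions(6.5, 1)))
  expect_gt(poisson_gof(counts)$p_value, 0.05)
  expect_identical(simulate_class2_positions(0, 1), numeric(0))
  expect_error(simulate_class2_positions(-1, 1), "rate")
})

test_that("simulated cells respect pathway knockouts and shape scoring", {
  cfg <- sim_config("hei10", n_cells = 30, seed = 3)
  expect_identical(cfg$class1_mu, 0)
  sim <- simulate_meiosis(cfg)
  expect_identical(nrow(sim$foci), 0L)  # no bright foci without class I
  # shape class is a deterministic function of total event count
  tot <- sim$cells$n_class1 + sim$cells$n_class2
  expect_identical(sim$cells$shape_class,
                   c("univalent_pair", "rod", "ring")[pmin(tot, 2) + 1])
})

test_that("WT cells carry ~24 bright foci, mostly 1-3 per bivalent", {
  sim <- simulate_meiosis(sim_config("WT", n_cells = 200, seed = 5))
  bright <- sim$foci[sim$foci$channel == "bright", ]
  per_cell <- tabulate(factor(bright$cell_id,
                              levels = unique(sim$cells$cell_id)))
  expect_equal(mean(per_cell), 24, tolerance = 0.05)
  per_biv <- table(paste(bright$cell_id, bright$bivalent_id))
  expect_gt(mean(per_biv %in% 1:3), 0.95)
})

test_that("seeded simulations are reproducible and seeds distinguish runs", {
  a <- simulate_meiosis(sim_config("WT", n_cells = 10, seed = 9))
  b <- simulate_meiosis(sim_config("WT", n_cells = 10, seed = 9))
  expect_identical(a, b)
  c <- simulate_meiosis(sim_config("WT", n_cells = 10, seed = 10))
  expect_false(identical(a$cells, c$cells))
})

test_that("dual-channel generator is exact with no noise and validates inputs", {
  base <- make_foci(c(0.1, 0.4, 0.9))
  dual <- simulate_dual_channel(base, jitter_sd = 0, dropout_a = 0,
                                dropout_b = 0, extra_rate = 0)
  a <- dual[dual$channel == "A", "position_frac"]
  b <- dual[dual$channel == "B", "position_frac"]
  expect_identical(a, base$position_frac)
  expect_identical(b, base$position_frac)
  expect_error(simulate_dual_channel(base, dropout_a = 1.2), "\\[0, 1\\]")
  expect_error(simulate_dual_channel(base, jitter_sd = -1), "jitter_sd")
})

test_that("colocalization is monotone non-increasing in jitter at fixed tolerance", {
  sim <- simulate_meiosis(sim_config("WT", n_cells = 150, seed = 13))
  base <- sim$foci[sim$foci$channel == "bright",
                   c("cell_id", "bivalent_id", "position_frac")]
  fracs <- vapply(c(0, 0.005, 0.02, 0.08), function(js) {
    set.seed(99)
    dual <- simulate_dual_channel(base, jitter_sd = js, dropout_a = 0,
                                  dropout_b = 0)
    co <- coloc_fractions(dual[dual$channel == "A", ],
                          dual[dual$channel == "B", ], tolerance = 0.01)
    co$fraction_a_with_b
  }, 0)
  expect_true(all(diff(fracs) <= 0))
  expect_lt(fracs[[4]], fracs[[1]])
})

test_that("genotype defaults reproduce published focus-count calibrations", {
  simz <- simulate_meiosis(sim_config("zep1", n_cells = 150, seed = 17))
  per_cell <- table(simz$foci$cell_id)
  expect_equal(mean(per_cell), 36.2, tolerance = 0.03)
  simp <- simulate_meiosis(sim_config("pair3", n_cells = 300, seed = 19))
  expect_equal(nrow(simp$foci) / 300, 1.2, tolerance = 0.25)
})
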