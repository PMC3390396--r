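test_that("inter-focus distances are interior gaps in percent of SC length", {
  d <- interfocus_distances(c(0.10, 0.55, 0.90))
  expect_equal(d$distances, c(45, 35))
  expect_identical(d$n, 2L)
  # one focus contributes nothing
  expect_identical(interfocus_distances(0.5)$n, 0L)
  expect_error(interfocus_distances(c(0.2, 1.4)), "\\[0, sc_length\\]")
  # raw micron-like coordinates normalised by sc_length
  d2 <- interfocus_distances(c(2, 11, 18), sc_length = 20)
  expect_equal(d2$distances, c(45, 35))
})

test_that("distance extraction pools per cell and chromosome", {
  foci <- rbind(make_foci(c(0.1, 0.6), cell = "c1"),
                make_foci(0.5, cell = "c2"),          # single focus: excluded
                make_foci(c(0.2, 0.3, 0.9), cell = "c3"))
  d <- interfocus_distances(foci)
  expect_identical(d$n, 3L)
  expect_setequal(round(d$distances), c(50, 10, 60))
})

test_that("extracted gaps from a stationary renewal match the gamma model (KS)", {
  set.seed(53)
  # long SC so window truncation is negligible: the end-segment-exclusion
  # convention then recovers gaps that are exactly Gamma(nu, rate nu * mu);
  # distances come back as percent of SC length
  L <- 2000
  pos <- simulate_class1_positions(8.39, 2, L)
  d <- interfocus_distances(pos, sc_length = L)
  expect_gt(d$n, 1000)
  ks <- stats::ks.test(d$distances * L / 100, "pgamma", shape = 8.39,
                       rate = 8.39 * 2)
  expect_gt(ks$p.value, 0.01)
})

test_that("short-window truncation biases observed gaps short, as documented", {
  set.seed(54)
  # on unit-length chromosomes with ~2 foci each, gaps lying wholly inside
  # the window under-sample long gaps; the observed mean must fall below the
  # unconditional gamma gap mean (1/mu = 0.5, i.e. 50% of SC)
  foci <- do.call(rbind, lapply(1:2000, function(i)
    make_foci(simulate_class1_positions(8.39, 2, 1), cell = paste0("c", i))))
  d <- interfocus_distances(foci)
  expect_gt(d$n, 500)
  expect_lt(mean(d$distances), 50)
})

test_that("the MLE recovers the generating shape across interference strengths", {
  for (nu in c(1, 2, 4, 8.39, 12)) {
    set.seed(round(100 * nu))
    gaps <- rgamma(5000, shape = nu, scale = 7)
    fit <- fit_interference(gaps, method = "mle")
    expect_equal(fit$nu, nu, tolerance = 0.05)
    expect_equal(fit$scale * fit$nu, mean(gaps), tolerance = 1e-8)
    # method-of-moments oracle agrees within 10%
    mom <- fit_interference(gaps, method = "mom")
    expect_lt(abs(fit$nu - mom$nu) / fit$nu, 0.10)
  }
})

test_that("the MLE agrees with an independent gamma fitter", {
  skip_if_not_installed("MASS")
  set.seed(59)
  gaps <- rgamma(2000, shape = 8.39, scale = 3)
  ours <- fit_interference(gaps)
  ref <- suppressWarnings(MASS::fitdistr(gaps, "gamma"))
  expect_equal(ours$nu, unname(ref$estimate[["shape"]]), tolerance = 1e-4)
  expect_equal(ours$se_nu, unname(ref$sd[["shape"]]), tolerance = 1e-2)
  expect_equal(ours$loglik, unname(ref$loglik), tolerance = 1e-6)
})

test_that("no-interference data fit to shape ~ 1", {
  set.seed(61)
  fit <- fit_interference(rgamma(5000, shape = 1, scale = 2))
  expect_lt(abs(fit$nu - 1), 3 * fit$se_nu)
})

test_that("degenerate near-constant gaps give a huge shape without crashing", {
  set.seed(67)
  gaps <- 10 + rnorm(100, sd = 1e-4)
  fit <- fit_interference(gaps)
  expect_gt(fit$nu, 1e4)
  expect_gt(fit$se_nu, 1e3)
  expect_error(fit_interference(c(1, 2)), "at least 3")
  expect_error(fit_interference(c(0, 1, 2)), "> 0")
})

test_that("the binned least-squares fit is consistent with the MLE", {
  set.seed(71)
  gaps <- rgamma(3000, shape = 8.39, scale = 3)
  mle <- fit_interference(gaps, method = "mle")
  binned <- fit_interference(gaps, method = "binned", n_bins = 12)
  expect_lt(abs(binned$nu - mle$nu) / mle$nu, 0.15)
  set.seed(73)
  b1 <- fit_interference(rgamma(3000, shape = 1, scale = 2),
                         method = "binned", n_bins = 12)
  expect_equal(b1$nu, 1, tolerance = 0.2)
  expect_warning(fit_interference(rgamma(40, 2, 1), method = "binned",
                                  n_bins = 30), "too fine")
  expect_error(fit_interference(rgamma(10, 2, 1), method = "binned"),
               "at least 20")
})

test_that("the Fisher SE shrinks as 1/sqrt(n)", {
  set.seed(79)
  ns <- c(250, 1000, 4000, 16000)
  ses <- vapply(ns, function(n)
    fit_interference(rgamma(n, shape = 8.39, scale = 3))$se_nu, 0)
  slope <- coef(stats::lm(log(ses) ~ log(ns)))[[2]]
  expect_lt(abs(slope + 0.5), 0.1)
})

test_that("bootstrap SE is close to the Fisher SE on well-behaved data", {
  set.seed(83)
  gaps <- rgamma(800, shape = 4, scale = 5)
  fisher <- fit_interference(gaps)$se_nu
  boot <- fit_interference(gaps, se = "bootstrap", n_boot = 300,
                           boot_seed = 7)$se_nu
  expect_equal(boot, fisher, tolerance = 0.25)
})

test_that("stronger generative interference strictly lowers the empirical gap CV", {
  cvs <- vapply(c(1, 2, 4, 8.39, 12), function(nu) {
    set.seed(97)
    p <- simulate_class1_positions(nu, mu = 2, length = 2000)
    g <- diff(p)
    sd(g) / mean(g)
  }, 0)
  expect_true(all(diff(cvs) < 0))
})

test_that("gamma_fit behaves like a standard model object", {
  set.seed(101)
  gaps <- rgamma(1000, shape = 8.39, scale = 3)
  fit <- fit_interference(gaps)
  expect_named(coef(fit), c("shape", "scale"))
  expect_identical(attr(logLik(fit), "nobs"), 1000L)
  v <- vcov(fit)
  expect_identical(dim(v), c(2L, 2L))
  expect_equal(sqrt(v[1, 1]), fit$se_nu, tolerance = 1e-10)
  ci <- confint(fit)
  expect_lt(ci[[1]], fit$nu)
  expect_gt(ci[[2]], fit$nu)
  expect_identical(simulate(fit, nsim = 50, seed = 3),
                   simulate(fit, nsim = 50, seed = 3))
  r <- residuals(fit)
  expect_equal(mean(r), 0, tolerance = 0.1)
  expect_equal(sd(r), 1, tolerance = 0.1)
  expect_output(print(summary(fit)), "interference")
  png_file <- tempfile(fileext = ".png")
  grDevices::png(png_file)
  plot(fit)
  grDevices::dev.off()
  expect_true(file.exists(png_file))
  unlink(png_file)
})
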