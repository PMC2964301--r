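test_that("hill_response satisfies its identities and limits", {
  p <- list(i_max = 1, ec50 = 91.1, n_h = 1.65)
  expect_equal(hill_response(91.1, p), 0.5)
  expect_equal(hill_response(0, p), 0)
  expect_equal(hill_response(1e12, p), 1, tolerance = 1e-6)
  ## independent hand evaluation of the formula at A = 30
  expect_equal(hill_response(30, p), 0.137910437255, tolerance = 1e-10)
  expect_error(hill_response(-1, p), "non-negative")
  ## monotone in concentration and linear in i_max
  conc <- 10^seq(-1, 3, length.out = 50)
  v <- hill_response(conc, p)
  expect_true(all(diff(v) > 0))
  p2 <- p; p2$i_max <- 3.7
  expect_equal(hill_response(conc, p2), 3.7 * v)
})

test_that("rundown correction inverts a constructed decline and is identity without rundown", {
  conc <- c(1000, 300, 100, 30, 10, 3)
  truth <- list(i_max = 5, ec50 = 50, n_h = 1.5)
  resp <- hill_response(conc, truth)

  ## no rundown: all standards equal -> output identical to input
  cell0 <- make_cell("c0", conc, resp, std_conc = 20, std_resp = c(1, 1, 1))
  expect_equal(rundown_correct(cell0)$applications$response,
               cell0$applications$response)

  ## standards declining linearly to 80%, tests scaled by the same decline
  cell <- make_cell("c1", conc, resp, std_conc = 20, std_resp = c(1, 1, 1))
  a <- cell$applications
  n_app <- nrow(a)
  decline <- seq(1, 0.8, length.out = n_app)
  a$response <- a$response * decline
  cell$applications <- a
  corr <- rundown_correct(cell)
  got <- corr$applications$response[!corr$applications$is_standard]
  expect_equal(got, resp, tolerance = 1e-12)
  ## standards map onto the first standard's value
  expect_equal(unique(round(corr$applications$response[corr$applications$is_standard], 12)),
               corr$applications$response[corr$applications$is_standard][1])

  ## single standard only -> error telling the user to skip explicitly
  one_std <- make_cell("c2", conc, resp, std_conc = 20, std_resp = 1)
  expect_error(rundown_correct(one_std), "skip")
})

test_that("fit_hill recovers noiseless truth exactly and fails below 4 concentrations", {
  ## 1:1 oocyte wild-type values
  d <- hill_points(2050, 172, 1.56)
  f <- fit_hill(d)
  expect_true(f$converged)
  expect_equal(f$i_max, 2050, tolerance = 1e-6)
  expect_equal(f$ec50, 172, tolerance = 1e-6)
  expect_equal(f$n_h, 1.56, tolerance = 1e-6)

  d3 <- hill_points(2050, 172, 1.56, conc = c(50, 170, 500))
  expect_error(fit_hill(d3), "insufficient")
})

test_that("fit_hill covers the truth under multiplicative noise", {
  set.seed(7)
  truth <- list(i_max = 2050, ec50 = 172, n_h = 1.56)
  d <- hill_points(truth$i_max, truth$ec50, truth$n_h)
  d$response <- d$response * exp(rnorm(8, 0, sqrt(log(1 + 0.05^2))))
  f <- fit_hill(d)
  expect_true(f$converged)
  ## recovered EC50 within the fit's own ~95% Wald interval
  expect_lt(abs(f$ec50 - truth$ec50), 2 * f$se[["ec50"]])
})

test_that("scaling responses scales i_max and leaves ec50 and n_h unchanged", {
  d <- hill_points(1, 91.1, 1.65)
  set.seed(11)
  d$response <- d$response * exp(rnorm(8, 0, 0.03))
  f1 <- fit_hill(d)
  d2 <- d; d2$response <- d2$response * 7.3
  f2 <- fit_hill(d2)
  expect_equal(f2$i_max / f1$i_max, 7.3, tolerance = 1e-5)
  expect_equal(f2$ec50, f1$ec50, tolerance = 1e-6)
  expect_equal(f2$n_h, f1$n_h, tolerance = 1e-6)
})

test_that("parallel_fit returns exact construction ratios and self-ratio 1", {
  conc <- 91.1 * 10^seq(-1.5, 1.5, length.out = 8)
  c1 <- hill_points(1, 91.1, 1.5, conc)
  c2 <- hill_points(1, 5.51, 1.5, conc / 10)
  pf <- parallel_fit(list(wt = c1, mut = c2), reference = "wt", intervals = FALSE)
  expect_equal(pf$dose_ratios[["mut"]], 5.51 / 91.1, tolerance = 1e-6)
  expect_equal(pf$dose_ratios[["wt"]], 1)
  expect_equal(pf$shared_n_h, 1.5, tolerance = 1e-6)

  ## two identical (duplicated) noisy curves -> ratio 1, interval straddles 1
  set.seed(21)
  a <- hill_points(1, 91.1, 1.5, conc)
  a$response <- a$response * exp(rnorm(8, 0, 0.04))
  pf2 <- parallel_fit(list(x = a, y = a), reference = "x")
  li <- pf2$likelihood_intervals["y", ]
  expect_equal(pf2$dose_ratios[["y"]], 1, tolerance = 1e-6)
  expect_true(li[["low"]] <= 1 && 1 <= li[["high"]])
  expect_lt(li[["low"]], 1 - 1e-4)
  expect_gt(li[["high"]], 1 + 1e-4)
})

test_that("parallel fit on shifted copies of one curve returns the construction ratios", {
  conc <- 50 * 10^seq(-1.5, 1.5, length.out = 8)
  base <- hill_points(1, 50, 1.7, conc)
  ratios <- c(1, 0.25, 3.5)
  curves <- list(ref = base,
                 a = hill_points(1, 50 * 0.25, 1.7, conc * 0.25),
                 b = hill_points(1, 50 * 3.5, 1.7, conc * 3.5))
  pf <- parallel_fit(curves, reference = "ref", intervals = FALSE)
  expect_equal(unname(pf$dose_ratios[c("ref", "a", "b")]), ratios, tolerance = 1e-6)
})

test_that("log dose ratio inverts exactly when the reference is relabelled", {
  conc <- 91.1 * 10^seq(-1.2, 1.2, length.out = 8)
  set.seed(31)
  a <- hill_points(1, 91.1, 1.6, conc)
  b <- hill_points(1, 30, 1.6, conc / 3)
  a$response <- a$response * exp(rnorm(8, 0, 0.03))
  b$response <- b$response * exp(rnorm(8, 0, 0.03))
  f1 <- parallel_fit(list(p = a, q = b), reference = "p", intervals = FALSE)
  f2 <- parallel_fit(list(p = a, q = b), reference = "q", intervals = FALSE)
  expect_equal(log(f1$dose_ratios[["q"]]), -log(f2$dose_ratios[["p"]]),
               tolerance = 1e-5)
})

test_that("non-parallel curves trigger the lack-of-parallelism diagnostic", {
  ## genuinely different slopes (0.9 vs 2.4) with mild noise
  conc <- 100 * 10^seq(-1.5, 1.5, length.out = 10)
  set.seed(41)
  a <- hill_points(1, 100, 0.9, conc)
  b <- hill_points(1, 40, 2.4, conc)
  a$response <- a$response * exp(rnorm(10, 0, 0.02))
  b$response <- b$response * exp(rnorm(10, 0, 0.02))
  pf <- parallel_fit(list(sh = a, st = b), reference = "sh", intervals = FALSE)
  expect_true(is.finite(pf$parallelism$f))
  expect_lt(pf$parallelism$p, 0.01)
  expect_gt(pf$parallelism$rss_parallel, pf$parallelism$rss_free)
})

test_that("normalize_pool scales each cell to its fitted maximum", {
  conc <- c(1000, 300, 100, 30, 10, 3, 500, 50)
  truth <- list(i_max = 1800, ec50 = 90, n_h = 1.6)
  resp <- hill_response(conc, truth)
  cells <- list(make_cell("a", conc, resp, receptor = "wt"),
                make_cell("b", conc, resp * 0.4, receptor = "wt"))
  pooled <- normalize_pool(cells)
  expect_named(pooled, "wt")
  expect_equal(nrow(pooled$wt), 16)
  ## both cells collapse onto the same normalized curve
  expect_equal(pooled$wt$response[1:8], pooled$wt$response[9:16], tolerance = 1e-6)
  expect_lt(max(pooled$wt$response), 1.01)
})
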