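## partial-curve cell built from Hill feet with equal slopes
foot_cell <- function(id, ec50s, n_h = 2.2, i_max = 1000, noise = 0,
                      n_pts = 3, frac = c(0.01, 0.03, 0.08)) {
  rows <- lapply(names(ec50s), function(ag) {
    ## concentrations giving responses at the stated small fractions of max
    conc <- ec50s[[ag]] * (frac / (1 - frac))^(1 / n_h)
    conc <- conc[seq_len(n_pts)]
    r <- i_max * conc^n_h / (conc^n_h + ec50s[[ag]]^n_h)
    data.frame(agonist = ag, concentration = conc, response = r)
  })
  d <- do.call(rbind, rows)
  if (noise > 0) d$response <- d$response * exp(rnorm(nrow(d), 0, noise))
  partial_curve_set(id, d)
}

test_that("parallel power-law fit reads off exact constructed shifts", {
  ## two agonists on one line shifted horizontally by exactly 1 log unit
  conc <- c(1, 3, 10)
  d <- rbind(data.frame(agonist = "ACh", concentration = conc,
                        response = 10 * conc^1.8),
             data.frame(agonist = "X", concentration = conc / 10,
                        response = 10 * conc^1.8))
  f <- fit_parallel_powerlaw(partial_curve_set("c", d))
  expect_equal(f$potency_ratio[["X"]], 10, tolerance = 1e-8)
  expect_equal(f$dose_ratio[["X"]], 0.1, tolerance = 1e-8)
  expect_equal(f$potency_ratio[["ACh"]], 1)
  expect_equal(f$slope, 1.8, tolerance = 1e-10)
})

test_that("potency ratio from Hill feet recovers the EC50 ratio under mild noise", {
  ## 9:1 oocyte design: ACh EC50 309.5 uM, DMPP 30.3 uM, same slope
  set.seed(17)
  reps <- 40
  est <- replicate(reps, {
    cell <- foot_cell("c", c(ACh = 309.5, DMPP = 30.3), noise = 0.02)
    fit_parallel_powerlaw(cell)$potency_ratio[["DMPP"]]
  })
  expect_equal(mean(est), 309.5 / 30.3,
               tolerance = 3 * sd(est) / sqrt(reps) / (309.5 / 30.3))
})

test_that("potency ratios are exactly scale-equivariant in concentration", {
  set.seed(19)
  cell <- foot_cell("c", c(ACh = 300, DMPP = 30), noise = 0.02)
  f1 <- fit_parallel_powerlaw(cell)
  p2 <- cell$points
  k <- 4.7
  p2$concentration[p2$agonist == "DMPP"] <- p2$concentration[p2$agonist == "DMPP"] * k
  f2 <- fit_parallel_powerlaw(partial_curve_set("c", p2))
  expect_equal(f2$potency_ratio[["DMPP"]], f1$potency_ratio[["DMPP"]] / k,
               tolerance = 1e-8)
})

test_that("free-slope fits recover exact slopes and the low-concentration Hill limit", {
  conc <- c(1, 2, 5, 10)
  d <- rbind(data.frame(agonist = "ACh", concentration = conc,
                        response = 2 * conc^2),
             data.frame(agonist = "X", concentration = conc,
                        response = 5 * conc^2))
  s <- fit_free_slopes(partial_curve_set("c", d))
  expect_equal(s$slope, c(2, 2), tolerance = 1e-10)

  ## as concentrations shrink below the EC50, the log-log slope tends to n_h
  n_h <- 1.45
  slope_at <- function(scale) {
    conc <- 100 * scale * c(1, 2, 4)
    r <- conc^n_h / (conc^n_h + 100^n_h)
    d <- rbind(data.frame(agonist = "ACh", concentration = conc, response = r),
               data.frame(agonist = "ACh2", concentration = conc, response = r))
    d$agonist <- rep(c("ACh", "X"), each = 3)
    fit_free_slopes(partial_curve_set("c", d))$slope[1]
  }
  expect_equal(slope_at(1e-3), n_h, tolerance = 1e-3)
  expect_gt(abs(slope_at(0.5) - n_h), 0.1)  # far from the limit at high conc
})

test_that("agonists with a single point are skipped with a warning", {
  d <- rbind(data.frame(agonist = "ACh", concentration = c(1, 3, 10),
                        response = c(2, 8, 30)),
             data.frame(agonist = "Y", concentration = c(2, 6),
                        response = c(9, 35)),
             data.frame(agonist = "X", concentration = 1, response = 5))
  expect_warning(f <- fit_parallel_powerlaw(partial_curve_set("c", d)),
                 "skipped")
  expect_false("X" %in% names(f$potency_ratio))
  expect_false(is.na(f$potency_ratio[["Y"]]))
  ## skipping leaves fewer than two agonists -> error
  expect_error(fit_parallel_powerlaw(partial_curve_set("c", d[c(1:3, 6), ])),
               ">= 2 agonists")
})

test_that("degenerate Fieller reduces to the delta-method interval", {
  ## zero-variance denominator, zero covariance
  num <- 1.2; den <- 2; var_num <- 0.04; tv <- 2
  fl <- fieller_interval(num, den, var_num, 0, 0, tv)
  expect_equal(fl[["low"]], num / den - tv * sqrt(var_num) / den)
  expect_equal(fl[["high"]], num / den + tv * sqrt(var_num) / den)
  expect_false(attr(fl, "unbounded"))
  ## g >= 1 flags an unbounded interval instead of raising
  fl2 <- fieller_interval(1, 0.1, 0.01, 1, 0, 2)
  expect_true(attr(fl2, "unbounded"))
  expect_error(fieller_interval(1, 0, 0.1, 0.1, 0, 2), "nonzero")
})

test_that("Fieller bounds match a parametric bootstrap oracle", {
  ## toy joint-normal numerator/denominator
  num <- 0.8; den <- 1.9
  V <- matrix(c(0.0225, 0.006, 0.006, 0.0144), 2)
  zv <- qnorm(0.975)
  fl <- fieller_interval(num, den, V[1, 1], V[2, 2], V[1, 2], zv)
  set.seed(11)
  n_draw <- 1e5
  z <- matrix(rnorm(2 * n_draw), ncol = 2) %*% chol(V)
  draws <- (num + z[, 1]) / (den + z[, 2])
  q <- quantile(draws, c(0.025, 0.975))
  expect_equal(fl[["low"]], q[[1]], tolerance = 0.02)
  expect_equal(fl[["high"]], q[[2]], tolerance = 0.02)
})

test_that("Fieller interval on the log scale contains the estimate", {
  set.seed(23)
  cell <- foot_cell("c", c(ACh = 300, DMPP = 30), noise = 0.03)
  f <- fit_parallel_powerlaw(cell)
  expect_true(f$ci["DMPP", "low"] <= f$potency_ratio[["DMPP"]])
  expect_true(f$ci["DMPP", "high"] >= f$potency_ratio[["DMPP"]])
})

test_that("pooling recovers the true potency across cells", {
  ## identical ratios -> SEM 0
  cellA <- foot_cell("a", c(ACh = 300, DMPP = 30))
  cellB <- cellA; cellB$cell_id <- "b"
  pot0 <- pool_potency(list(cellA, cellB))
  expect_equal(pot0$sem[pot0$agonist == "DMPP"], 0, tolerance = 1e-10)

  ## two-alpha design: true DMPP/ACh potency ~1 over 9 cells
  set.seed(29)
  cells1 <- lapply(1:9, function(i)
    foot_cell(paste0("c", i), c(ACh = 137.8, DMPP = 137.8 / 0.99), noise = 0.02))
  p1 <- pool_potency(cells1)
  row1 <- p1[p1$agonist == "DMPP", ]
  expect_lt(abs(row1$potency_ratio - 0.99), 3 * row1$sem + 0.02)

  ## three-alpha design: true potency 10 over 8 cells
  cells2 <- lapply(1:8, function(i)
    foot_cell(paste0("d", i), c(ACh = 309.5, DMPP = 30.95), noise = 0.02))
  p2 <- pool_potency(cells2)
  row2 <- p2[p2$agonist == "DMPP", ]
  expect_lt(abs(row2$potency_ratio - 10), 3 * row2$sem + 0.2)

  ## an agonist present in one cell only: mean reported, SEM flagged absent
  cells3 <- list(foot_cell("e1", c(ACh = 300, DMPP = 30, Nic = 100)),
                 foot_cell("e2", c(ACh = 300, DMPP = 30)))
  p3 <- pool_potency(cells3)
  expect_true(p3$single_cell[p3$agonist == "Nic"])
  expect_true(is.na(p3$sem[p3$agonist == "Nic"]))
})

test_that("rank order of a six-agonist panel is preserved under noise", {
  ## potencies patterned on the 9:1 panel
  true_pot <- c(Epibatidine = 6260, Lobeline = 17.7, Nicotine = 2.95,
                Cytisine = 1.92, DMPP = 10.2, Carbachol = 0.093)
  ec50s <- c(ACh = 309.5, 309.5 / true_pot)
  names(ec50s) <- c("ACh", names(true_pot))
  set.seed(37)
  n_ok <- 0; reps <- 40
  for (i in seq_len(reps)) {
    cell <- foot_cell("c", ec50s, noise = 0.02)
    est <- fit_parallel_powerlaw(cell)$potency_ratio[names(true_pot)]
    n_ok <- n_ok + identical(order(est), order(true_pot))
  }
  expect_gte(n_ok / reps, 0.95)
})
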