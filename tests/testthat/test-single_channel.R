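test_that("resolvable-opening filter applies the rise-time rule", {
  rec <- idealized_record(
    data.frame(state = c("open", "shut", "open", "shut", "open"),
               duration_ms = c(0.5, 5, 0.7, 5, 3),
               amplitude_pA = c(2.5, NA, 2.6, NA, 2.7)),
    holding_potential = -100, filter_cutoff = 1, resolution = 100)
  out <- filter_resolvable(rec)
  ## T_r = 0.3321 / 1 kHz ~ 0.332 ms; 0.5 ms excluded, 0.7 ms retained
  expect_equal(attr(out, "rise_time_ms"), 0.3321)
  expect_equal(out$duration_ms, c(0.7, 3))
  expect_equal(attr(out, "n_excluded"), 1L)

  ## all openings far above 2 T_r -> all retained
  rec2 <- idealized_record(
    data.frame(state = c("open", "shut", "open"),
               duration_ms = c(10, 5, 20), amplitude_pA = c(2, NA, 3)),
    holding_potential = -100, filter_cutoff = 1, resolution = 100)
  expect_equal(nrow(filter_resolvable(rec2)), 2)

  expect_error(idealized_record(rec$events, -100, 0, 100), "filter_cutoff")
})

test_that("amplitude mixture recovers one- and two-class truth", {
  set.seed(5)
  amp1 <- rnorm(300, 2.7, 0.3)
  m1 <- fit_amplitude_mixture(amp1)
  expect_equal(m1$k, 1)
  expect_lt(abs(m1$components$mean - 2.7), 3 * 0.3 / sqrt(300))
  expect_equal(sum(m1$components$area), 1)

  set.seed(6)
  n2 <- 500
  lab <- runif(n2) < 0.27
  amp2 <- ifelse(lab, rnorm(n2, 2.6, 0.5), rnorm(n2, 3.9, 0.4))
  m2 <- fit_amplitude_mixture(amp2, k = 2)
  expect_equal(m2$k, 2)
  expect_true(all(diff(m2$components$mean) > 0))
  expect_lt(abs(m2$components$area[1] - 0.27), 0.08)
  expect_lt(abs(m2$components$mean[1] - 2.6), 0.2)
  expect_lt(abs(m2$components$mean[2] - 3.9), 0.2)

  expect_error(fit_amplitude_mixture(rnorm(50, 2.7, 0.3)), "insufficient")
})

test_that("model selection prefers one component for single-Gaussian data", {
  set.seed(61)
  n_one <- 0; reps <- 50
  for (i in seq_len(reps)) {
    m <- fit_amplitude_mixture(rnorm(200, 2.7, 0.3))
    n_one <- n_one + (m$k == 1)
  }
  expect_gte(n_one / reps, 0.9)
})

test_that("chord conductance reproduces the published values and its symmetries", {
  expect_equal(chord_conductance(2.6, -100, 0), 26)
  expect_equal(chord_conductance(3.9, -100, 0), 39)
  expect_equal(chord_conductance(0, -100, 0), 0)
  ## linear in amplitude, invariant to the sign of the driving force
  expect_equal(chord_conductance(5.2, -100, 0), 2 * chord_conductance(2.6, -100, 0))
  expect_equal(chord_conductance(2.6, 100, 0), chord_conductance(2.6, -100, 0))
  expect_error(chord_conductance(2.6, 0, 0), "differ")
})

test_that("burst segmentation matches hand enumeration on the toy event list", {
  rec <- toy_record()
  ## shut times 0.2, 8, 0.3 ms with tcrit 2 ms -> bursts {2 openings, 2 openings}
  bs <- segment_bursts(rec, tcrit = 2)
  expect_equal(nrow(bs$bursts), 2)
  expect_equal(bs$bursts$n_openings, c(2L, 2L))
  ## durations by hand: 1 + 0.2 + 2 = 3.2 and 1.5 + 0.3 + 0.5 = 2.3
  expect_equal(bs$bursts$duration_ms, c(3.2, 2.3))
  expect_equal(bs$bursts$open_time_ms, c(3, 2))

  ## tcrit above every shut time -> one burst; below -> one burst per opening
  expect_equal(nrow(segment_bursts(rec, tcrit = 100)$bursts), 1)
  expect_equal(nrow(segment_bursts(rec, tcrit = 0.1)$bursts), 4)
})

test_that("burst segmentation conserves open time and is monotone in tcrit", {
  sim <- simulate_single_channel(default_channel_classes(0.3),
                                 record_duration = 30, seed = 71)
  rec <- sim$record
  total_open <- sum(rec$events$duration_ms[rec$events$state == "open"])
  n_openings <- sum(rec$events$state == "open")
  tcrits <- c(0.2, 1, 5, 20, 100, 1000)
  counts <- vapply(tcrits, function(tc) {
    bs <- segment_bursts(rec, tc)
    expect_equal(sum(bs$bursts$open_time_ms), total_open, tolerance = 1e-9)
    expect_equal(sum(bs$bursts$n_openings), n_openings)
    nrow(bs$bursts)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("per-class burst statistics assign classes and flag outliers", {
  mix <- structure(list(components = data.frame(mean = c(2.6, 3.9),
                                                sd = c(0.5, 0.4),
                                                area = c(0.27, 0.73)),
                        k = 2L, n_openings_used = 500L, bic = NA_real_),
                   class = "amplitude_mixture")
  events <- data.frame(
    state = c("open", "shut", "open", "shut", "open"),
    duration_ms = c(5, 50, 4, 50, 3),
    amplitude_pA = c(2.5, NA, 3.8, NA, 10))
  rec <- idealized_record(events, -100, 1, 100)
  bs <- segment_bursts(rec, tcrit = 10)
  st <- burst_class_stats(bs, mix)
  expect_setequal(st$class, c("class1", "class2", "unassigned"))
  expect_equal(st$n_bursts[st$class == "unassigned"], 1)
  expect_equal(sum(st$proportion), 1)
  ## conductance of class1 ~ 2.5 pA at -100 mV -> 25 pS
  expect_equal(st$mean_conductance_pS[st$class == "class1"], 25)

  ## single-component mixture -> one class holding all bursts
  mix1 <- structure(list(components = data.frame(mean = 2.6, sd = 0.5, area = 1),
                         k = 1L, n_openings_used = 300L, bic = NA_real_),
                    class = "amplitude_mixture")
  events1 <- events; events1$amplitude_pA <- c(2.5, NA, 2.7, NA, 2.4)
  st1 <- burst_class_stats(segment_bursts(idealized_record(events1, -100, 1, 100),
                                          10), mix1)
  expect_equal(nrow(st1), 1)
  expect_equal(st1$proportion, 1)
})

test_that("two-class records yield the expected class burst durations", {
  sim <- simulate_single_channel(default_channel_classes(0.3),
                                 record_duration = 150, seed = 73)
  res <- filter_resolvable(sim$record)
  mix <- fit_amplitude_mixture(res$amplitude_pA, k = 2)
  bs <- segment_bursts(sim$record, tcrit = 5)
  st <- burst_class_stats(bs, mix)
  low <- st[st$class == "class1", ]; high <- st[st$class == "class2", ]
  ## long low-conductance bursts (~100 ms) vs short high-conductance (~14 ms)
  expect_lt(abs(low$mean_duration_ms - 100), 3 * low$sem_duration_ms + 10)
  expect_lt(abs(high$mean_duration_ms - 14), 3 * high$sem_duration_ms + 2)
  expect_lt(abs(low$mean_conductance_pS - 26), 2)
  expect_lt(abs(high$mean_conductance_pS - 39), 2)
})

test_that("cross-class transition diagnostic counts constructed adjacencies", {
  mix <- structure(list(components = data.frame(mean = c(2.6, 3.9),
                                                sd = c(0.1, 0.1),
                                                area = c(0.5, 0.5)),
                        k = 2L, n_openings_used = 500L, bic = NA_real_),
                   class = "amplitude_mixture")
  ## two same-class adjacencies, no cross-class within tcrit
  clean <- idealized_record(
    data.frame(state = c("open", "shut", "open", "shut", "open"),
               duration_ms = c(2, 1, 2, 50, 2),
               amplitude_pA = c(2.6, NA, 2.6, NA, 3.9)),
    -100, 1, 100)
  expect_equal(count_class_transitions(clean, mix, tcrit = 5), 0L)
  ## a direct low-to-high adjacency inside one burst is counted
  mixed <- idealized_record(
    data.frame(state = c("open", "shut", "open"),
               duration_ms = c(2, 1, 2),
               amplitude_pA = c(2.6, NA, 3.9)),
    -100, 1, 100)
  expect_equal(count_class_transitions(mixed, mix, tcrit = 5), 1L)
})
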