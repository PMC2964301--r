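#' Dose-response simulation scenario
#'
#' Describes a population of simulated cells: the true Hill curve per
#' receptor set, multiplicative lognormal noise on peak currents,
#' geometric per-application rundown, and the application protocol
#' (descending doses with a standard ~EC20 application every third
#' response).  Defaults mirror a typical wild-type whole-cell experiment:
#' EC50 91.1 uM, Hill slope 1.65, maximum 6.67 nA, 5% noise, 8
#' half-log-spaced concentrations, 6 cells.
#'
#' @param true_hill list with `i_max`, `ec50`, `n_h` (the generating
#'   truth).
#' @param noise_cv coefficient of variation of the multiplicative
#'   lognormal response noise (>= 0; default 0.05).
#' @param rundown_per_application fractional response loss per
#'   application, compounded (in [0, 0.1); default 0.02).
#' @param n_cells number of cells (default 6).
#' @param concentrations test concentrations in uM, used in descending
#'   order (default 8 half-log steps bracketing the EC50).
#' @param standard_every a standard application every this many responses
#'   (default 3).
#' @return An object of class `dose_response_scenario`.
#' @export
dose_response_scenario <- function(true_hill = list(i_max = 6.67, ec50 = 91.1, n_h = 1.65),
                                   noise_cv = 0.05,
                                   rundown_per_application = 0.02,
                                   n_cells = 6,
                                   concentrations = NULL,
                                   standard_every = 3) {
  stopifnot(noise_cv >= 0,
            rundown_per_application >= 0, rundown_per_application < 0.1,
            n_cells >= 1, standard_every >= 2)
  stopifnot(true_hill$i_max > 0, true_hill$ec50 > 0, true_hill$n_h > 0)
  if (is.null(concentrations)) {
    concentrations <- true_hill$ec50 * 10^seq(-1.75, 1.75, length.out = 8)
  }
  if (length(concentrations) == 0) stop("empty concentration list")
  structure(list(true_hill = true_hill,
                 noise_cv = noise_cv,
                 rundown_per_application = rundown_per_application,
                 n_cells = as.integer(n_cells),
                 concentrations = sort(concentrations, decreasing = TRUE),
                 standard_every = as.integer(standard_every)),
            class = "dose_response_scenario")
}

## EC20 of a Hill curve: EC50 * (0.2/0.8)^(1/n)
.ec20 <- function(truth) truth$ec50 * 0.25^(1 / truth$n_h)

## multiplicative lognormal noise factors with mean 1 and given cv
.lognoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate dose-response cells
#'
#' Per cell: peak responses on the true Hill curve, multiplied by the
#' compounded rundown factor for their application index and by
#' mean-one lognormal noise; standard (~EC20) applications are
#' interleaved every `standard_every` responses, opening and closing the
#' protocol so rundown correction can bracket every test response.
#'
#' @param scenario a [dose_response_scenario()].
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @param receptor receptor label attached to the cells.
#' @param cell_prefix prefix for cell ids.
#' @return List with elements `cells` (list of [dose_response_cell()])
#'   and `truth` (the generating parameters: the ground-truth sidecar).
#' @export
simulate_dose_response <- function(scenario, seed = NULL, receptor = "wt",
                                   cell_prefix = receptor) {
  stopifnot(inherits(scenario, "dose_response_scenario"))
  if (!is.null(seed)) set.seed(seed)
  truth <- scenario$true_hill
  std_conc <- .ec20(truth)
  std_resp <- hill_response(std_conc, truth)
  conc <- scenario$concentrations
  ## protocol: standard first, one every (standard_every - 1) tests, standard last
  agonist <- character(0); c_app <- numeric(0); is_std <- logical(0)
  n_between <- scenario$standard_every - 1L
  i <- 1
  while (i <= length(conc)) {
    agonist <- c(agonist, "ACh_std"); c_app <- c(c_app, std_conc); is_std <- c(is_std, TRUE)
    take <- seq(i, min(i + n_between - 1, length(conc)))
    agonist <- c(agonist, rep("ACh", length(take)))
    c_app <- c(c_app, conc[take]); is_std <- c(is_std, rep(FALSE, length(take)))
    i <- i + n_between
  }
  agonist <- c(agonist, "ACh_std"); c_app <- c(c_app, std_conc); is_std <- c(is_std, TRUE)
  n_app <- length(c_app)
  true_resp <- ifelse(is_std, std_resp, hill_response(c_app, truth))
  cells <- lapply(seq_len(scenario$n_cells), function(ic) {
    rd <- (1 - scenario$rundown_per_application)^(seq_len(n_app) - 1)
    resp <- true_resp * rd * .lognoise(n_app, scenario$noise_cv)
    dose_response_cell(
      cell_id = sprintf("%s_cell%02d", cell_prefix, ic),
      applications = data.frame(application_index = seq_len(n_app),
                                agonist = agonist,
                                concentration = c_app,
                                response = resp,
                                is_standard = is_std),
      receptor = receptor)
  })
  list(cells = cells,
       truth = list(true_hill = truth, standard_concentration = std_conc,
                    noise_cv = scenario$noise_cv,
                    rundown_per_application = scenario$rundown_per_application,
                    receptor = receptor))
}

#' Simulate a reporter-mutation panel (wild type, alpha- and beta-mutant)
#'
#' Generates three dose-response data sets sharing everything except the
#' EC50: under the unitary-shift model with per-copy factor `r` and
#' subunit copy numbers `assignment`, the mutant EC50s are
#' `wt_ec50 / r^copies` for the mutated subunit's copy count.
#'
#' @param wild_type list with `i_max`, `ec50`, `n_h` for the wild type.
#' @param r per-copy potency factor (>= 1).
#' @param assignment named integer vector `c(alpha = , beta = )` summing
#'   to 5, each copy count 2 or 3.
#' @param seed integer seed.
#' @param ... further arguments to [dose_response_scenario()]
#'   (noise_cv, n_cells, ...), shared by the three sets.
#' @return List with `sets` (named list wt/alpha/beta of
#'   `simulate_dose_response()` outputs) and `truth` (the sidecar:
#'   assignment, r, per-set EC50s).
#' @export
simulate_mutation_panel <- function(wild_type, r, assignment = c(alpha = 3L, beta = 2L),
                                    seed = NULL, ...) {
  if (!isTRUE(r >= 1)) stop("r must be >= 1")
  if (!setequal(names(assignment), c("alpha", "beta")) ||
      sum(assignment) != 5 || !all(assignment %in% 2:3)) {
    stop("assignment must be c(alpha=, beta=) with copies in {2,3} summing to 5")
  }
  if (!is.null(seed)) set.seed(seed)
  ec50s <- c(wt = wild_type$ec50,
             alpha = wild_type$ec50 / r^assignment[["alpha"]],
             beta = wild_type$ec50 / r^assignment[["beta"]])
  sets <- lapply(names(ec50s), function(nm) {
    th <- wild_type; th$ec50 <- ec50s[[nm]]
    sc <- dose_response_scenario(true_hill = th, ...)
    simulate_dose_response(sc, seed = NULL, receptor = nm)
  })
  names(sets) <- names(ec50s)
  list(sets = sets,
       truth = list(assignment = assignment, r = r, ec50 = ec50s,
                    wild_type = wild_type))
}

#' Simulate a zinc modulation curve
#'
#' Normalized responses from either a biphasic truth (fields `w`,
#' `max_effect`, `min_effect`, `ec50_zn`, `ic50_zn`, `n_h1`, `n_h2`,
#' evaluated by [biphasic_response()]) or a single-Hill inhibition truth
#' (fields `ic50_zn`, `n_h`, optional `amplitude`), with mean-one
#' lognormal noise.
#'
#' @param truth the generating model (see above).
#' @param concentrations zinc concentrations in uM (default 10 half-log
#'   steps from 10 uM to 10 mM, emulating the tested range).
#' @param noise_cv lognormal noise cv (default 0.05).
#' @param seed integer seed.
#' @param cell_id label.
#' @return List with `curve` (a [zinc_curve()]) and `truth` (sidecar).
#' @export
simulate_zinc_curve <- function(truth,
                                concentrations = 10^seq(1, 4, length.out = 10),
                                noise_cv = 0.05, seed = NULL,
                                cell_id = "sim") {
  if (!is.null(seed)) set.seed(seed)
  x <- log10(concentrations)
  mu <- if (!is.null(truth$w)) {
    biphasic_response(x, truth)
  } else {
    amp <- if (is.null(truth$amplitude)) 1 else truth$amplitude
    1 - amp * .logistic10(x, truth$ic50_zn, truth$n_h)
  }
  y <- pmax(mu * .lognoise(length(mu), noise_cv), 0)
  list(curve = zinc_curve(data.frame(zinc_concentration = concentrations,
                                     normalized_response = y),
                          cell_id = cell_id),
       truth = truth)
}

#' Single-channel class specification
#'
#' One conductance class of channel activity: Gaussian open-level
#' amplitudes, exponential open/shut durations, and the burst skeleton
#' (openings per burst, within-burst gaps shorter than between-burst
#' gaps).  Defaults are not provided: the two classes of the default
#' panel are built by [default_channel_classes()].
#'
#' @param amplitude_mean,amplitude_sd pA.
#' @param mean_burst_duration ms (first opening start to last opening
#'   end).
#' @param mean_openings_per_burst expected openings per burst (>= 1).
#' @param within_burst_gap_mean,between_burst_gap_mean ms; within must be
#'   shorter than between.
#' @param relative_frequency fraction of bursts from this class.
#' @return An object of class `channel_class_spec`.
#' @export
channel_class_spec <- function(amplitude_mean, amplitude_sd,
                               mean_burst_duration, mean_openings_per_burst,
                               within_burst_gap_mean, between_burst_gap_mean,
                               relative_frequency) {
  stopifnot(amplitude_mean > 0, amplitude_sd > 0,
            mean_burst_duration > 0, mean_openings_per_burst >= 1,
            within_burst_gap_mean > 0,
            within_burst_gap_mean < between_burst_gap_mean,
            relative_frequency > 0, relative_frequency <= 1)
  open_total <- mean_burst_duration -
    (mean_openings_per_burst - 1) * within_burst_gap_mean
  if (open_total <= 0) {
    stop("burst skeleton infeasible: gaps exceed the mean burst duration")
  }
  structure(list(amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd,
                 mean_burst_duration = mean_burst_duration,
                 mean_openings_per_burst = mean_openings_per_burst,
                 within_burst_gap_mean = within_burst_gap_mean,
                 between_burst_gap_mean = between_burst_gap_mean,
                 relative_frequency = relative_frequency,
                 mean_open_duration = open_total / mean_openings_per_burst),
            class = "channel_class_spec")
}

#' Default two-class single-channel panel
#'
#' The two conductance classes seen in outside-out patches: a
#' low-conductance class (2.6 pA at -100 mV, 26 pS) opening in long
#' bursts (~100 ms) and a high-conductance class (3.9 pA, 39 pS) with
#' short bursts (~14 ms); the low class contributes a small fraction of
#' bursts (defaults 8% vs 92%, as in mixed patches).
#'
#' @param low_fraction fraction of bursts from the low-conductance class
#'   (default 0.08).
#' @return List of two [channel_class_spec()] objects, `low` and `high`.
#' @export
default_channel_classes <- function(low_fraction = 0.08) {
  list(
    low = channel_class_spec(amplitude_mean = 2.6, amplitude_sd = 0.5,
                             mean_burst_duration = 100,
                             mean_openings_per_burst = 20,
                             within_burst_gap_mean = 0.5,
                             between_burst_gap_mean = 500,
                             relative_frequency = low_fraction),
    high = channel_class_spec(amplitude_mean = 3.9, amplitude_sd = 0.4,
                              mean_burst_duration = 14,
                              mean_openings_per_burst = 5,
                              within_burst_gap_mean = 0.5,
                              between_burst_gap_mean = 500,
                              relative_frequency = 1 - low_fraction)
  )
}

## merge events shorter than the resolution into the ongoing resolved event
## (standard resolution-imposition rule); never produces non-positive durations
.impose_resolution <- function(events, res_ms) {
  keep_from <- which(events$duration_ms >= res_ms)[1]
  if (is.na(keep_from)) stop("no event as long as the resolution")
  cur <- events[keep_from, ]
  cur_open_ms <- if (cur$state == "open") cur$duration_ms else 0
  cur_amp_wt <- if (cur$state == "open") cur$amplitude_pA * cur$duration_ms else 0
  out <- vector("list", nrow(events))
  n_out <- 0
  j <- keep_from + 1
  while (j <= nrow(events)) {
    ev <- events[j, ]
    if (ev$duration_ms < res_ms || ev$state == cur$state) {
      cur$duration_ms <- cur$duration_ms + ev$duration_ms
      if (cur$state == "open" && ev$state == "open") {
        cur_open_ms <- cur_open_ms + ev$duration_ms
        cur_amp_wt <- cur_amp_wt + ev$amplitude_pA * ev$duration_ms
      }
    } else {
      if (cur$state == "open") cur$amplitude_pA <- cur_amp_wt / cur_open_ms
      n_out <- n_out + 1; out[[n_out]] <- cur
      cur <- ev
      cur_open_ms <- if (cur$state == "open") cur$duration_ms else 0
      cur_amp_wt <- if (cur$state == "open") cur$amplitude_pA * cur$duration_ms else 0
    }
    j <- j + 1
  }
  if (cur$state == "open") cur$amplitude_pA <- cur_amp_wt / cur_open_ms
  n_out <- n_out + 1; out[[n_out]] <- cur
  do.call(rbind, out[seq_len(n_out)])
}

#' Simulate an idealized single-channel record
#'
#' Draws bursts from the class mix (class picked by relative frequency
#' per burst), with exponential open and shut durations, Gaussian
#' amplitudes per opening, and exponential between-burst shut intervals;
#' then imposes the stated resolution by merging unresolvable events.
#' Per-burst true class labels are returned as the ground-truth sidecar.
#'
#' @param classes list of [channel_class_spec()] objects; relative
#'   frequencies must sum to 1.
#' @param record_duration target record length in seconds (default 60).
#' @param resolution imposed resolution in microseconds (default 100).
#' @param seed integer seed.
#' @param holding_potential mV (default -100).
#' @param filter_cutoff kHz (default 1).
#' @return List with `record` (an [idealized_record()]) and `truth`
#'   (data frame of per-burst class labels and the class specs).
#' @export
simulate_single_channel <- function(classes, record_duration = 60,
                                    resolution = 100, seed = NULL,
                                    holding_potential = -100,
                                    filter_cutoff = 1) {
  stopifnot(length(classes) >= 1)
  freqs <- vapply(classes, `[[`, numeric(1), "relative_frequency")
  stopifnot(abs(sum(freqs) - 1) < 1e-6)
  if (is.null(names(classes))) names(classes) <- paste0("class", seq_along(classes))
  res_ms <- resolution / 1000
  min_gap <- min(vapply(classes, `[[`, numeric(1), "within_burst_gap_mean"))
  if (resolution / 1000 >= min_gap) {
    warning("resolution is not shorter than the within-burst gap mean: severe censoring")
  }
  if (!is.null(seed)) set.seed(seed)
  target_ms <- record_duration * 1000
  ev_state <- character(0); ev_dur <- numeric(0); ev_amp <- numeric(0)
  truth_class <- character(0)
  t_total <- 0
  repeat {
    ci <- sample(seq_along(classes), 1, prob = freqs)
    cl <- classes[[ci]]
    ## leading inter-burst shut interval
    gap <- stats::rexp(1, 1 / cl$between_burst_gap_mean)
    n_open <- stats::rgeom(1, 1 / cl$mean_openings_per_burst) + 1L
    opens <- stats::rexp(n_open, 1 / cl$mean_open_duration)
    amps <- abs(stats::rnorm(n_open, cl$amplitude_mean, cl$amplitude_sd))
    gaps <- if (n_open > 1) stats::rexp(n_open - 1, 1 / cl$within_burst_gap_mean) else numeric(0)
    st <- c("shut", rep(c("open", "shut"), n_open))[seq_len(2 * n_open)]
    du <- numeric(2 * n_open); am <- rep(NA_real_, 2 * n_open)
    du[1] <- gap
    du[seq(2, 2 * n_open, by = 2)] <- opens
    am[seq(2, 2 * n_open, by = 2)] <- amps
    if (n_open > 1) du[seq(3, 2 * n_open - 1, by = 2)] <- gaps
    ev_state <- c(ev_state, st); ev_dur <- c(ev_dur, du); ev_amp <- c(ev_amp, am)
    truth_class <- c(truth_class, names(classes)[ci])
    t_total <- t_total + sum(du)
    if (t_total >= target_ms) break
  }
  events <- data.frame(state = ev_state, duration_ms = ev_dur,
                       amplitude_pA = ev_amp)
  events <- .impose_resolution(events, res_ms)
  record <- idealized_record(events, holding_potential = holding_potential,
                             filter_cutoff = filter_cutoff,
                             resolution = resolution)
  list(record = record,
       truth = list(burst_class = truth_class, classes = classes))
}
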