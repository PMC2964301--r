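#' Construct an idealized single-channel record
#'
#' An alternating open/shut event sequence produced by time-course
#' idealization (this package consumes event lists; it does not idealize
#' raw traces), together with the recording metadata needed downstream:
#' holding potential, low-pass filter cutoff and the imposed resolution.
#'
#' @param events data frame with columns `state` (`"open"`/`"shut"`,
#'   strictly alternating), `duration_ms` (> 0) and `amplitude_pA`
#'   (open events; `NA` for shut).
#' @param holding_potential mV (e.g. -100).
#' @param filter_cutoff low-pass cutoff in kHz (> 0).
#' @param resolution imposed resolution in microseconds (> 0).
#' @return An object of class `idealized_record`.
#' @export
idealized_record <- function(events, holding_potential, filter_cutoff, resolution) {
  req <- c("state", "duration_ms", "amplitude_pA")
  miss <- setdiff(req, names(events))
  if (length(miss)) stop("events missing column(s): ", paste(miss, collapse = ", "))
  stopifnot(filter_cutoff > 0, resolution > 0)
  if (!all(events$state %in% c("open", "shut"))) {
    stop("event state must be 'open' or 'shut'")
  }
  if (nrow(events) > 1 && any(events$state[-1] == events$state[-nrow(events)])) {
    stop("open/shut states must strictly alternate")
  }
  if (any(events$duration_ms <= 0)) stop("event durations must be positive")
  if (any(events$duration_ms < resolution / 1000 - 1e-9)) {
    stop("events shorter than the imposed resolution are present; impose resolution first")
  }
  structure(list(events = events[, req],
                 holding_potential = holding_potential,
                 filter_cutoff = filter_cutoff,
                 resolution = resolution),
            class = "idealized_record")
}

#' @export
print.idealized_record <- function(x, ...) {
  e <- x$events
  cat(sprintf("<idealized_record: %d events (%d openings, total open %.4g ms) at %g mV, filter %g kHz, resolution %g us>\n",
              nrow(e), sum(e$state == "open"),
              sum(e$duration_ms[e$state == "open"]),
              x$holding_potential, x$filter_cutoff, x$resolution))
  invisible(x)
}

#' Filter openings with well-defined amplitudes
#'
#' An opening's amplitude is only fully resolved if the event outlasts
#' the filter's rise time; openings longer than twice the rise time
#' `T_r = k / f_c` (default `k = 0.3321`, the Gaussian-response value,
#' a close approximation for high-order Bessel filters) are retained for
#' amplitude analysis.  Excluded openings remain in the event sequence
#' (burst segmentation uses all events); they are only dropped from the
#' amplitude list.
#'
#' @param record an [idealized_record()].
#' @param rise_time_constant the constant `k` in `T_r = k / f_c`
#'   (default 0.3321).
#' @return Data frame of resolvable openings (`duration_ms`,
#'   `amplitude_pA`) with attributes `rise_time_ms` and `n_excluded`;
#'   zero rows (with a warning) if none survive.
#' @export
filter_resolvable <- function(record, rise_time_constant = 0.3321) {
  stopifnot(inherits(record, "idealized_record"))
  if (!isTRUE(record$filter_cutoff > 0)) stop("filter_cutoff must be positive")
  t_r <- rise_time_constant / record$filter_cutoff  # ms, cutoff in kHz
  op <- record$events[record$events$state == "open", c("duration_ms", "amplitude_pA")]
  keep <- op$duration_ms > 2 * t_r
  out <- op[keep, ]
  attr(out, "rise_time_ms") <- t_r
  attr(out, "n_excluded") <- sum(!keep)
  if (nrow(out) == 0) warning("no opening outlasts twice the filter rise time")
  out
}

#' Gaussian mixture fit of fitted open-level amplitudes
#'
#' Maximum-likelihood Gaussian mixture on the list of fitted amplitudes
#' (one point per opening, as in a fitted-amplitude histogram).  With
#' `k = "auto"` the number of components is chosen among 1-3 by BIC.
#' Components are returned in order of increasing mean with their areas
#' (mixing proportions) summing to 1.
#'
#' @param amplitudes numeric vector of open-level amplitudes (pA).
#' @param k number of components (1, 2, 3) or `"auto"`.
#' @param min_openings minimum number of amplitudes required
#'   (default 100, the conventional floor for a stable histogram fit).
#' @return List of class `amplitude_mixture` with a `components` data
#'   frame (`mean`, `sd`, `area`), `k`, `n_openings_used`, `bic`.
#' @importFrom mclust Mclust mclustBIC
#' @export
fit_amplitude_mixture <- function(amplitudes, k = "auto", min_openings = 100) {
  amplitudes <- amplitudes[is.finite(amplitudes)]
  if (length(amplitudes) < min_openings) {
    stop("insufficient data: ", length(amplitudes), " amplitudes, need >= ",
         min_openings)
  }
  G <- if (identical(k, "auto")) 1:3 else as.integer(k)
  stopifnot(all(G %in% 1:3))
  bic <- mclustBIC(amplitudes, G = G, modelNames = c("E", "V"),
                   verbose = FALSE)
  fit <- Mclust(amplitudes, x = bic, verbose = FALSE)
  if (is.null(fit)) stop("mixture fit failed")
  mu <- fit$parameters$mean
  sigma <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sigma) == 1) sigma <- rep(sigma, length(mu))
  pro <- fit$parameters$pro
  ord <- order(mu)
  structure(list(components = data.frame(mean = mu[ord], sd = sigma[ord],
                                         area = pro[ord]),
                 k = fit$G,
                 n_openings_used = length(amplitudes),
                 bic = fit$bic),
            class = "amplitude_mixture")
}

#' @export
print.amplitude_mixture <- function(x, ...) {
  cat(sprintf("<amplitude_mixture: %d component(s) from %d openings>\n",
              x$k, x$n_openings_used))
  co <- x$components
  for (i in seq_len(nrow(co))) {
    cat(sprintf("  %.3g +/- %.2g pA, area %.0f%%\n",
                co$mean[i], co$sd[i], 100 * co$area[i]))
  }
  invisible(x)
}

#' Chord conductance from amplitude and driving force
#'
#' `g = i / |V_hold - V_rev|`, returned in picosiemens for amplitude in
#' pA and potentials in mV.  The magnitude of the driving force is used,
#' so the sign convention of the holding potential does not matter.
#'
#' @param amplitude open-level amplitude (pA).
#' @param holding_potential mV.
#' @param reversal_potential mV (default 0, no junction-potential
#'   correction).
#' @return Chord conductance in pS.
#' @examples
#' chord_conductance(2.6, -100)  # 26 pS
#' @export
chord_conductance <- function(amplitude, holding_potential, reversal_potential = 0) {
  if (any(holding_potential == reversal_potential)) {
    stop("holding and reversal potentials must differ (zero driving force)")
  }
  amplitude / abs(holding_potential - reversal_potential) * 1000
}

#' Segment an event sequence into bursts
#'
#' Openings separated by shut intervals shorter than the critical shut
#' time `tcrit` are grouped into one burst; a shut time of `tcrit` or
#' longer ends the burst.  Burst duration runs from the first opening's
#' start to the last opening's end (so it includes the within-burst
#' gaps).  Total open time and opening count are conserved exactly for
#' any `tcrit`.
#'
#' @param record an [idealized_record()].
#' @param tcrit critical shut time in ms (must exceed the imposed
#'   resolution).
#' @return List of class `burst_set`: `bursts` data frame (`duration_ms`,
#'   `n_openings`, `mean_amplitude`, `open_time_ms`), `tcrit`, and the
#'   source record's metadata.
#' @export
segment_bursts <- function(record, tcrit) {
  stopifnot(inherits(record, "idealized_record"))
  if (!isTRUE(tcrit > record$resolution / 1000)) {
    stop("tcrit must exceed the imposed resolution")
  }
  e <- record$events
  is_open <- e$state == "open"
  if (!any(is_open)) {
    return(structure(list(bursts = data.frame(duration_ms = numeric(0),
                                              n_openings = integer(0),
                                              mean_amplitude = numeric(0),
                                              open_time_ms = numeric(0)),
                          tcrit = tcrit,
                          holding_potential = record$holding_potential),
                     class = "burst_set"))
  }
  ## a long shut interval between two openings splits bursts
  open_idx <- which(is_open)
  n_open <- length(open_idx)
  new_burst <- logical(n_open)
  new_burst[1] <- TRUE
  if (n_open > 1) {
    for (j in 2:n_open) {
      gap_rows <- (open_idx[j - 1] + 1):(open_idx[j] - 1)
      gap <- sum(e$duration_ms[gap_rows])
      new_burst[j] <- gap >= tcrit
    }
  }
  burst_id <- cumsum(new_burst)
  bursts <- do.call(rbind, lapply(split(seq_len(n_open), burst_id), function(jj) {
    rows <- open_idx[jj]
    span_rows <- rows[1]:rows[length(rows)]
    data.frame(duration_ms = sum(e$duration_ms[span_rows]),
               n_openings = length(rows),
               mean_amplitude = mean(e$amplitude_pA[rows]),
               open_time_ms = sum(e$duration_ms[rows]))
  }))
  rownames(bursts) <- NULL
  structure(list(bursts = bursts, tcrit = tcrit,
                 holding_potential = record$holding_potential),
            class = "burst_set")
}

#' @export
print.burst_set <- function(x, ...) {
  b <- x$bursts
  cat(sprintf("<burst_set: %d bursts (tcrit %g ms), mean duration %.4g ms, mean %.3g openings/burst>\n",
              nrow(b), x$tcrit,
              if (nrow(b)) mean(b$duration_ms) else NA,
              if (nrow(b)) mean(b$n_openings) else NA))
  invisible(x)
}

#' Per-conductance-class burst statistics
#'
#' Assigns every burst to the amplitude-mixture component with the
#' highest posterior density at the burst's mean amplitude; bursts whose
#' amplitude lies more than `z_threshold` SDs from every component are
#' left unassigned.  Summaries mirror the pooled burst-proportion and
#' burst-duration comparisons between conductance classes.
#'
#' @param bursts a [segment_bursts()] result.
#' @param mixture an [fit_amplitude_mixture()] result.
#' @param z_threshold outlier cut-off in component SDs (default 4).
#' @param reversal_potential mV, for the class conductances (default 0).
#' @return Data frame of class `burst_class_stats`: one row per class
#'   (plus `"unassigned"` if any), with burst count, proportion of all
#'   bursts, mean duration +/- SEM, mean amplitude and mean chord
#'   conductance.
#' @export
burst_class_stats <- function(bursts, mixture, z_threshold = 4,
                              reversal_potential = 0) {
  stopifnot(inherits(bursts, "burst_set"), inherits(mixture, "amplitude_mixture"))
  co <- mixture$components
  stopifnot(nrow(co) >= 1)
  b <- bursts$bursts
  if (nrow(b) == 0) stop("empty burst set")
  dens <- sapply(seq_len(nrow(co)), function(i) {
    co$area[i] * stats::dnorm(b$mean_amplitude, co$mean[i], co$sd[i])
  })
  dens <- matrix(dens, nrow = nrow(b))
  zmin <- apply(abs(outer(b$mean_amplitude, co$mean, "-")) /
                  matrix(co$sd, nrow(b), nrow(co), byrow = TRUE), 1, min)
  cls <- ifelse(zmin > z_threshold, 0L, apply(dens, 1, which.max))
  labels <- paste0("class", seq_len(nrow(co)))
  out <- lapply(c(seq_len(nrow(co)), if (any(cls == 0)) 0L), function(i) {
    rows <- b[cls == i, ]
    n <- nrow(rows)
    data.frame(
      class = if (i == 0) "unassigned" else labels[i],
      n_bursts = n,
      proportion = n / nrow(b),
      mean_duration_ms = if (n) mean(rows$duration_ms) else NA_real_,
      sem_duration_ms = if (n > 1) stats::sd(rows$duration_ms) / sqrt(n) else NA_real_,
      mean_amplitude_pA = if (n) mean(rows$mean_amplitude) else NA_real_,
      mean_conductance_pS = if (n) {
        chord_conductance(mean(rows$mean_amplitude),
                          bursts$holding_potential, reversal_potential)
      } else NA_real_
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("burst_class_stats", "data.frame")
  out
}

#' Count direct transitions between conductance classes
#'
#' Diagnostic: within each burst-free event stretch, direct open-to-open
#' level changes between mixture components would indicate one channel
#' visiting both conductance levels.  Counts openings that are adjacent
#' (separated by a single shut interval shorter than `tcrit`) but
#' assigned to different components.
#'
#' @param record an [idealized_record()].
#' @param mixture an [fit_amplitude_mixture()] result.
#' @param tcrit ms.
#' @return Integer count of cross-class adjacencies.
#' @export
count_class_transitions <- function(record, mixture, tcrit) {
  stopifnot(inherits(record, "idealized_record"))
  co <- mixture$components
  e <- record$events
  open_idx <- which(e$state == "open")
  if (length(open_idx) < 2 || nrow(co) < 2) return(0L)
  assign_one <- function(a) {
    which.max(co$area * stats::dnorm(a, co$mean, co$sd))
  }
  cls <- vapply(e$amplitude_pA[open_idx], assign_one, integer(1))
  n_trans <- 0L
  for (j in 2:length(open_idx)) {
    gap <- sum(e$duration_ms[(open_idx[j - 1] + 1):(open_idx[j] - 1)])
    if (gap < tcrit && cls[j] != cls[j - 1]) n_trans <- n_trans + 1L
  }
  n_trans
}
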