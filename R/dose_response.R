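#' Construct a single-cell dose-response record
#'
#' One cell's (or oocyte's) ordered sequence of agonist applications,
#' including the interleaved standard-agonist applications (approximately
#' EC20) used to monitor and correct for rundown.  Responses are peak
#' inward currents recorded as magnitudes (nA).
#'
#' @param cell_id cell label.
#' @param applications data frame with columns `application_index`,
#'   `agonist`, `concentration` (uM, positive), `response` (nA,
#'   non-negative) and `is_standard` (logical).
#' @param receptor optional receptor-set label (e.g. `"wt"`, `"alpha"`,
#'   `"beta"`), carried through to the stoichiometry stage.
#' @return An object of class `dose_response_cell`.
#' @export
dose_response_cell <- function(cell_id, applications, receptor = NA_character_) {
  req <- c("application_index", "agonist", "concentration", "response", "is_standard")
  miss <- setdiff(req, names(applications))
  if (length(miss)) stop("applications missing column(s): ", paste(miss, collapse = ", "))
  applications <- applications[order(applications$application_index), req]
  bad <- which(!(applications$concentration > 0))
  if (length(bad)) {
    stop("non-positive concentration in cell ", cell_id,
         " at application ", applications$application_index[bad[1]])
  }
  if (any(applications$response < 0)) {
    stop("negative response in cell ", cell_id,
         " (responses are magnitudes of inward current)")
  }
  std <- applications[applications$is_standard, ]
  if (nrow(std) > 0 &&
      (length(unique(std$agonist)) > 1 || length(unique(std$concentration)) > 1)) {
    stop("standard applications in cell ", cell_id,
         " must all use one agonist at one concentration")
  }
  structure(list(cell_id = as.character(cell_id),
                 applications = applications,
                 receptor = as.character(receptor)),
            class = "dose_response_cell")
}

#' @export
print.dose_response_cell <- function(x, ...) {
  a <- x$applications
  cat(sprintf("<dose_response_cell '%s'%s: %d applications (%d standards), agonist(s) %s>\n",
              x$cell_id,
              if (is.na(x$receptor)) "" else paste0(" [", x$receptor, "]"),
              nrow(a), sum(a$is_standard),
              paste(unique(a$agonist[!a$is_standard]), collapse = "/")))
  invisible(x)
}

#' Hill equation response
#'
#' Evaluates the Hill equation
#' \deqn{I = I_{max} \frac{A^{n_H}}{A^{n_H} + EC_{50}^{n_H}}}
#' where `A` is the agonist concentration.  The curve is monotone
#' non-decreasing in `A`, passes through `i_max / 2` exactly at
#' `A == ec50`, and tends to 0 and `i_max` at the extremes.
#'
#' @param concentration agonist concentration(s), uM, non-negative.
#' @param params a `hill_fit` object or a list with elements `i_max`,
#'   `ec50` and `n_h`.
#' @return Predicted response(s), same length as `concentration`.
#' @examples
#' hill_response(91.1, list(i_max = 1, ec50 = 91.1, n_h = 1.65))  # 0.5
#' @export
hill_response <- function(concentration, params) {
  if (any(concentration < 0)) stop("concentration must be non-negative")
  i_max <- params$i_max; ec50 <- params$ec50; n_h <- params$n_h
  stopifnot(i_max > 0, ec50 > 0, n_h > 0)
  ## computed on the log-concentration scale for numerical range safety
  r <- (concentration / ec50)^n_h
  ifelse(is.infinite(r), i_max, i_max * r / (1 + r))
}

#' Correct a cell's responses for rundown
#'
#' Uses the standard-agonist applications interleaved through the
#' experiment: the standard response is linearly interpolated in
#' application index, and every response is rescaled by
#' (first standard response) / (interpolated standard response), so that
#' the standards themselves map onto the first standard's value.
#'
#' @param cell a [dose_response_cell()].
#' @return A corrected `dose_response_cell`.
#' @export
rundown_correct <- function(cell) {
  stopifnot(inherits(cell, "dose_response_cell"))
  a <- cell$applications
  std <- a[a$is_standard, ]
  if (nrow(std) < 2) {
    stop("rundown correction needs at least 2 standard applications; ",
         "cell '", cell$cell_id, "' has ", nrow(std),
         ". To proceed without correction, skip rundown_correct() explicitly.")
  }
  interp <- stats::approx(std$application_index, std$response,
                          xout = a$application_index, rule = 2)$y
  a$response <- a$response * std$response[1] / interp
  cell$applications <- a
  cell
}

## least-squares Hill fit on (concentration, response) vectors.
## Parameters are kept on the natural scale with positivity lower bounds;
## an estimate landing on a bound is reported as a failed fit, not clipped.
.fit_hill_xy <- function(conc, resp) {
  n_pts <- length(conc)
  resid_fn <- function(p) resp - p[1] * (conc / p[2])^p[3] / (1 + (conc / p[2])^p[3])
  half <- max(resp) / 2
  ec50_0 <- conc[which.min(abs(resp - half))]
  starts <- list(
    c(max(resp) * 1.05, ec50_0, 1.5),
    c(max(resp) * 1.05, exp(mean(log(conc))), 1.0),
    c(max(resp) * 1.50, ec50_0, 2.5),
    c(max(resp) * 1.05, ec50_0, 0.8)
  )
  lower <- c(1e-9, 1e-9, 1e-3)
  upper <- c(Inf, Inf, 50)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid_fn, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance)) best <- fit
  }
  if (is.null(best)) {
    return(list(converged = FALSE, message = "optimizer failed from all starts"))
  }
  p <- best$par
  on_bound <- any(abs(p - lower) < 1e-8 * pmax(1, abs(lower))) || p[3] >= upper[3] - 1e-6
  se <- tryCatch(summary(best)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  list(i_max = p[1], ec50 = p[2], n_h = p[3],
       se = c(i_max = se[1], ec50 = se[2], n_h = se[3]),
       rss = best$deviance, n_points = n_pts, df = n_pts - 3L,
       converged = !on_bound,
       message = if (on_bound) "estimate on parameter bound" else "ok")
}

#' Fit the Hill equation to one cell's dose-response curve
#'
#' Equal-weight least squares on the non-standard applications of a single
#' cell (each cell is fitted separately).  Standard errors come from the
#' approximate covariance at the optimum.  A fit whose optimum lands on a
#' parameter bound is reported as failed rather than silently clipped.
#'
#' @param cell a [dose_response_cell()], or a data frame with columns
#'   `concentration` and `response`.
#' @return An object of class `hill_fit` with elements `i_max`, `ec50`,
#'   `n_h` (all positive), `se`, `rss`, `n_points`, `converged`.
#' @export
fit_hill <- function(cell) {
  if (inherits(cell, "dose_response_cell")) {
    a <- cell$applications
    a <- a[!a$is_standard, ]
    conc <- a$concentration; resp <- a$response
    id <- cell$cell_id
  } else {
    conc <- cell$concentration; resp <- cell$response
    id <- "data"
  }
  if (length(unique(conc)) < 4) {
    stop("insufficient data: Hill fit needs >= 4 distinct concentrations (cell '",
         id, "' has ", length(unique(conc)), ")")
  }
  out <- .fit_hill_xy(conc, resp)
  out$cell_id <- id
  class(out) <- "hill_fit"
  if (is.null(out$i_max)) {
    out$converged <- FALSE
  }
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("<hill_fit: FAILED -", x$message, ">\n")
  } else {
    cat(sprintf("<hill_fit '%s': I_max = %.4g (SE %.3g), EC50 = %.4g uM (SE %.3g), n_H = %.3g (SE %.3g), RSS = %.4g on %d points>\n",
                x$cell_id, x$i_max, x$se[["i_max"]], x$ec50, x$se[["ec50"]],
                x$n_h, x$se[["n_h"]], x$rss, x$n_points))
  }
  invisible(x)
}

#' Normalize cells to their fitted maxima and pool per curve
#'
#' Each cell's non-standard responses are divided by that cell's own
#' fitted `i_max`, then cells belonging to the same receptor set are
#' pooled into one normalized curve, the substrate of [parallel_fit()].
#'
#' @param cells list of [dose_response_cell()] objects.
#' @param by how to group cells into curves: `"receptor"` (default) uses
#'   each cell's receptor label, `"cell"` keeps cells separate.
#' @return Named list of data frames (`concentration`, `response`).
#' @export
normalize_pool <- function(cells, by = c("receptor", "cell")) {
  by <- match.arg(by)
  stopifnot(length(cells) > 0)
  key <- vapply(cells, function(cl) {
    if (by == "receptor") cl$receptor else cl$cell_id
  }, character(1))
  out <- list()
  for (k in unique(key)) {
    pieces <- lapply(cells[key == k], function(cl) {
      f <- fit_hill(cl)
      if (!isTRUE(f$converged)) {
        warning("cell '", cl$cell_id, "' dropped from pooling: ", f$message)
        return(NULL)
      }
      a <- cl$applications
      a <- a[!a$is_standard, ]
      data.frame(concentration = a$concentration, response = a$response / f$i_max)
    })
    out[[k]] <- do.call(rbind, pieces)
  }
  out
}

## residuals for the parallel Hill model.
## theta = (log n_h, log ec50_ref, log ratio_2..k, log i_max_1..k); the
## reference curve's log ratio is fixed at 0.
.parallel_resid <- function(theta, conc, resp, curve_idx, k, ref_pos) {
  n_h  <- exp(theta[1])
  ec50_ref <- exp(theta[2])
  log_ratio <- numeric(k)
  log_ratio[-ref_pos] <- theta[3:(k + 1)]
  i_max <- exp(theta[(k + 2):(2 * k + 1)])
  ec50 <- ec50_ref * exp(log_ratio)
  r <- (conc / ec50[curve_idx])^n_h
  resp - i_max[curve_idx] * r / (1 + r)
}

#' Parallel (equal-slope) fit of several dose-response curves
#'
#' Simultaneous least squares over pooled normalized curves with one
#' shared Hill slope; each curve's EC50 is parameterized as
#' `reference_ec50 * dose_ratio` with the reference curve's ratio fixed
#' at 1.  Dose ratios > 1 mean the curve sits to the right of
#' (is less potent than) the reference; the potency ratio is the
#' reciprocal.  A free-slope refit (each curve with its own slope)
#' provides a lack-of-parallelism diagnostic via an extra-sum-of-squares
#' F test.
#'
#' @param curves named list of data frames (`concentration`, `response`),
#'   e.g. from [normalize_pool()]; each must be individually fittable.
#' @param reference name of the reference curve.
#' @param likelihood_delta log-likelihood drop for the dose-ratio
#'   intervals (default 2.01 units, about +/- 2 SD).
#' @param intervals compute the profile-likelihood intervals now
#'   (default TRUE; set FALSE to defer to [likelihood_interval()], e.g.
#'   in large simulations where only the point estimates are needed).
#' @return An object of class `parallel_fit` with the shared slope,
#'   reference EC50, per-curve dose ratios with profile-likelihood
#'   intervals, and the parallelism diagnostic.
#' @export
parallel_fit <- function(curves, reference, likelihood_delta = 2.01,
                         intervals = TRUE) {
  stopifnot(is.list(curves), length(curves) >= 2)
  if (!reference %in% names(curves)) {
    stop("reference curve '", reference, "' not among curves: ",
         paste(names(curves), collapse = ", "))
  }
  k <- length(curves)
  nm <- names(curves)
  ref_pos <- match(reference, nm)
  ind <- lapply(curves, fit_hill)
  bad <- !vapply(ind, function(f) isTRUE(f$converged), logical(1))
  if (any(bad)) stop("curve(s) not individually fittable: ",
                     paste(nm[bad], collapse = ", "))
  conc <- unlist(lapply(curves, `[[`, "concentration"), use.names = FALSE)
  resp <- unlist(lapply(curves, `[[`, "response"), use.names = FALSE)
  curve_idx <- rep(seq_len(k), vapply(curves, nrow, integer(1)))
  n_obs <- length(conc)

  start <- c(log(mean(vapply(ind, `[[`, numeric(1), "n_h"))),
             log(ind[[ref_pos]]$ec50),
             log(vapply(ind[-ref_pos], `[[`, numeric(1), "ec50") /
                 ind[[ref_pos]]$ec50),
             log(vapply(ind, `[[`, numeric(1), "i_max")))
  fit <- minpack.lm::nls.lm(
    par = start, fn = .parallel_resid,
    conc = conc, resp = resp, curve_idx = curve_idx, k = k, ref_pos = ref_pos,
    control = minpack.lm::nls.lm.control(maxiter = 1000))
  theta <- unname(fit$par)
  rss <- fit$deviance

  dose_ratios <- rep(1, k); names(dose_ratios) <- nm
  dose_ratios[-ref_pos] <- exp(theta[3:(k + 1)])

  ## free-slope model = independent Hill fits; nested comparison
  rss_free <- sum(vapply(ind, `[[`, numeric(1), "rss"))
  df_extra <- k - 1L
  df_free <- n_obs - 3L * k
  f_stat <- if (df_free > 0 && rss_free > 0) {
    ((rss - rss_free) / df_extra) / (rss_free / df_free)
  } else NA_real_
  p_par <- if (is.finite(f_stat)) stats::pf(f_stat, df_extra, df_free,
                                            lower.tail = FALSE) else NA_real_

  obj <- structure(list(
    shared_n_h = exp(theta[1]),
    reference_ec50 = exp(theta[2]),
    reference = reference,
    dose_ratios = dose_ratios,
    potency_ratios = 1 / dose_ratios,
    rss = rss, n_obs = n_obs, n_par = length(theta),
    theta = theta, ref_pos = ref_pos, k = k, curve_names = nm,
    data = list(conc = conc, resp = resp, curve_idx = curve_idx),
    parallelism = list(rss_parallel = rss, rss_free = rss_free,
                       f = f_stat, df = c(df_extra, df_free), p = p_par),
    likelihood_delta = likelihood_delta
  ), class = "parallel_fit")

  li <- matrix(NA_real_, k, 2, dimnames = list(nm, c("low", "high")))
  li[ref_pos, ] <- c(1, 1)
  if (intervals) {
    for (j in seq_len(k)[-ref_pos]) {
      li[j, ] <- likelihood_interval(obj, nm[j], delta = likelihood_delta)
    }
  }
  obj$likelihood_intervals <- li
  obj
}

#' @export
print.parallel_fit <- function(x, ...) {
  cat(sprintf("<parallel_fit: %d curves, shared n_H = %.3g, reference '%s' EC50 = %.4g uM>\n",
              x$k, x$shared_n_h, x$reference, x$reference_ec50))
  tab <- data.frame(dose_ratio = x$dose_ratios,
                    potency_ratio = x$potency_ratios,
                    low = x$likelihood_intervals[, "low"],
                    high = x$likelihood_intervals[, "high"])
  print(signif(tab, 4))
  pp <- x$parallelism
  cat(sprintf("parallelism: F(%d,%d) = %.3g, p = %.3g%s\n",
              pp$df[1], pp$df[2], pp$f, pp$p,
              if (is.finite(pp$p) && pp$p < 0.05) "  [curves not parallel]" else ""))
  invisible(x)
}

## profiled residual sum of squares: fix theta[fixed_idx] = value,
## re-optimize the remaining parameters (warm-started)
.profiled_rss <- function(value, fixed_idx, theta_start, resid_full, n_par) {
  free_idx <- setdiff(seq_len(n_par), fixed_idx)
  fn <- function(p_free) {
    th <- numeric(n_par)
    th[fixed_idx] <- value
    th[free_idx] <- p_free
    resid_full(th)
  }
  fit <- minpack.lm::nls.lm(par = theta_start[free_idx], fn = fn,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  th <- numeric(n_par); th[fixed_idx] <- value; th[free_idx] <- fit$par
  list(rss = fit$deviance, theta = th)
}

## outward search + uniroot for one side of a profile-likelihood interval
.profile_side <- function(est, dir, rss_target, prof, step0 = 0.1, max_double = 40) {
  step <- step0
  prev_v <- est
  state <- prof(est)
  for (i in seq_len(max_double)) {
    v <- est + dir * step
    state <- prof(v)
    if (state$rss >= rss_target) {
      root <- stats::uniroot(function(z) prof(z)$rss - rss_target,
                             lower = min(prev_v, v), upper = max(prev_v, v),
                             tol = 1e-8)
      return(root$root)
    }
    prev_v <- v
    step <- step * 2
  }
  dir * Inf  # profile never crossed the threshold: open interval
}

#' Profile-likelihood interval for a fitted parameter
#'
#' Interval based on the Gaussian profile log-likelihood with the noise
#' variance profiled out, so that the log-likelihood at parameter value
#' `v` is `-(n/2) log RSS(v)` up to a constant, with all remaining
#' parameters re-optimized at each `v`.  The interval endpoints are where
#' the profile falls `delta` units below its maximum; the default
#' `delta = 2.01` corresponds to about +/- 2 standard deviations for a
#' Gaussian parameter.  The search proceeds monotonically outward from
#' the estimate on each side; a side whose profile never crosses the
#' threshold is returned as infinite (open interval).
#'
#' @param fit a fitted object ([parallel_fit()] result, or for the
#'   default method a list with elements `resid` (function of the full
#'   parameter vector returning residuals), `theta` (estimate), `rss`
#'   and `n_obs`).
#' @param parameter which parameter to profile: a curve name for
#'   `parallel_fit` objects, a parameter index for the default method.
#' @param delta log-likelihood drop (> 0).
#' @param ... unused.
#' @return Numeric vector `c(low, high)` containing the point estimate.
#' @export
likelihood_interval <- function(fit, parameter, delta = 2.01, ...) {
  UseMethod("likelihood_interval")
}

#' @export
likelihood_interval.parallel_fit <- function(fit, parameter, delta = 2.01, ...) {
  stopifnot(delta > 0)
  j <- match(parameter, fit$curve_names)
  if (is.na(j)) stop("unknown curve '", parameter, "'")
  if (j == fit$ref_pos) return(c(low = 1, high = 1))
  pos_nonref <- which(seq_len(fit$k)[-fit$ref_pos] == j)
  idx <- 2 + pos_nonref  # position of this curve's log ratio in theta
  d <- fit$data
  resid_full <- function(th) .parallel_resid(th, d$conc, d$resp, d$curve_idx,
                                             fit$k, fit$ref_pos)
  rss_target <- fit$rss * exp(2 * delta / fit$n_obs)
  est <- fit$theta[idx]
  prof <- function(v) .profiled_rss(v, idx, fit$theta, resid_full, fit$n_par)
  lo <- .profile_side(est, -1, rss_target, prof, step0 = 0.05)
  hi <- .profile_side(est, +1, rss_target, prof, step0 = 0.05)
  c(low = exp(lo), high = exp(hi))
}

#' @export
likelihood_interval.default <- function(fit, parameter, delta = 2.01, ...) {
  stopifnot(delta > 0, is.function(fit$resid), is.numeric(fit$theta))
  idx <- parameter
  n_par <- length(fit$theta)
  rss_target <- fit$rss * exp(2 * delta / fit$n_obs)
  prof <- if (n_par == 1) {
    function(v) list(rss = sum(fit$resid(v)^2))
  } else {
    function(v) .profiled_rss(v, idx, fit$theta, fit$resid, n_par)
  }
  est <- fit$theta[idx]
  lo <- .profile_side(est, -1, rss_target, prof,
                      step0 = 0.1 * max(1e-3, abs(est)))
  hi <- .profile_side(est, +1, rss_target, prof,
                      step0 = 0.1 * max(1e-3, abs(est)))
  c(low = lo, high = hi)
}
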