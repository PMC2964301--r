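#' Construct a zinc modulation curve
#'
#' ACh responses (at an ~EC20 ACh concentration) in the presence of
#' increasing Zn2+ concentrations, each normalized to the response to
#' ACh alone, so that the zero-zinc control is 1 by construction.
#'
#' @param points data frame with columns `zinc_concentration` (uM, > 0)
#'   and `normalized_response` (>= 0).
#' @param ach_concentration the ACh concentration used (uM), metadata.
#' @param cell_id optional label.
#' @return An object of class `zinc_curve`.
#' @export
zinc_curve <- function(points, ach_concentration = NA_real_, cell_id = "pooled") {
  req <- c("zinc_concentration", "normalized_response")
  miss <- setdiff(req, names(points))
  if (length(miss)) stop("points missing column(s): ", paste(miss, collapse = ", "))
  stopifnot(all(points$zinc_concentration > 0),
            all(points$normalized_response >= 0))
  structure(list(points = points[, req],
                 ach_concentration = ach_concentration,
                 cell_id = as.character(cell_id)),
            class = "zinc_curve")
}

## base-10 logistic: half-activation at x = log10(c50), slope n
.logistic10 <- function(x, c50, n) 1 / (1 + 10^(n * (log10(c50) - x)))

#' Biphasic zinc modulation model
#'
#' Sum-of-two-logistics model for zinc modulation of the normalized ACh
#' response, as a function of `x = log10` zinc concentration (uM):
#' \deqn{I(x) = 1 + w (Max - 1) L(x; EC_{50}, n_{H1}) + (1 - w) Min\, L(x; IC_{50}, n_{H2})}
#' with `L` the base-10 logistic `1 / (1 + 10^{n (log10 c50 - x)})`.
#' The first component carries the enhancement (weight `w` in `[0, 1]`),
#' the second the inhibition (`Min` is negative for inhibition), and the
#' curve is anchored at the control value 1 as `x -> -Inf`.  Only the two
#' amplitude products `w (Max - 1)` and `(1 - w) Min` are identifiable
#' from a curve; fits report a canonical `(w, Max, Min)` derived from the
#' amplitudes (see [fit_biphasic()]).
#'
#' @param x log10 zinc concentration (zinc in uM).
#' @param fit a `biphasic_fit` or list with elements `w`, `max_effect`,
#'   `min_effect`, `ec50_zn`, `ic50_zn`, `n_h1`, `n_h2`.
#' @return Normalized response(s).
#' @export
biphasic_response <- function(x, fit) {
  w <- fit$w
  stopifnot(w >= 0, w <= 1, fit$ec50_zn > 0, fit$ic50_zn > 0,
            fit$n_h1 > 0, fit$n_h2 > 0)
  1 + w * (fit$max_effect - 1) * .logistic10(x, fit$ec50_zn, fit$n_h1) +
    (1 - w) * fit$min_effect * .logistic10(x, fit$ic50_zn, fit$n_h2)
}

## internal amplitude parameterization: theta = (A1, A2, log ec50, log ic50,
## log n1, log n2) with A1 = w(Max-1) >= 0 and A2 = (1-w)Min <= 0
.biphasic_value <- function(x, th) {
  1 + th[1] * .logistic10(x, exp(th[3]), exp(th[5])) +
    th[2] * .logistic10(x, exp(th[4]), exp(th[6]))
}

.biphasic_from_theta <- function(th, rss, n_obs) {
  a1 <- th[1]; a2 <- th[2]
  tot <- a1 + abs(a2)
  w <- if (tot > 0) a1 / tot else 1
  structure(list(
    w = w,
    max_effect = if (w > 0) 1 + a1 / w else 1,
    min_effect = if (w < 1) a2 / (1 - w) else 0,
    amp_enh = a1, amp_inh = a2,
    ec50_zn = exp(th[3]), ic50_zn = exp(th[4]),
    n_h1 = exp(th[5]), n_h2 = exp(th[6]),
    rss = rss, n_obs = n_obs, n_par = 6L,
    theta = th
  ), class = "biphasic_fit")
}

#' @export
print.biphasic_fit <- function(x, ...) {
  cat(sprintf("<biphasic_fit: enhancement %+.1f%% at EC50 %.4g uM (n_H1 %.3g); inhibition %.1f%% at IC50 %.4g uM (n_H2 %.3g); w = %.3g, RSS = %.4g>\n",
              100 * x$amp_enh, x$ec50_zn, x$n_h1,
              100 * x$amp_inh, x$ic50_zn, x$n_h2, x$w, x$rss))
  invisible(x)
}

## single-Hill inhibition-only model: I = 1 - a * L(x; ic50, n), a in (0, 1.2]
.single_value <- function(x, th) 1 - th[1] * .logistic10(x, exp(th[2]), exp(th[3]))

#' Fit zinc modulation: biphasic and single-Hill inhibition models
#'
#' Least-squares fits of (a) the biphasic sum-of-two-logistics model of
#' [biphasic_response()] and (b) a single-Hill inhibition-only model
#' `I = 1 - a L(x; IC50, nH)` to one zinc curve, both from multiple
#' deterministic starts.  Both fits are returned for model comparison by
#' [classify_modulation()].
#'
#' @param curve a [zinc_curve()]; needs at least 6 zinc concentrations
#'   spanning at least 2 log units.
#' @return List of class `zinc_fit_pair` with elements `biphasic`
#'   (`biphasic_fit` or NULL if it failed), `single` (list with
#'   `inhibition_amplitude`, `ic50_zn`, `n_h`, `rss`, ...), and the data.
#' @export
fit_biphasic <- function(curve) {
  stopifnot(inherits(curve, "zinc_curve"))
  p <- curve$points
  x <- log10(p$zinc_concentration)
  y <- p$normalized_response
  if (length(unique(x)) < 6 || diff(range(x)) < 2) {
    stop("insufficient data: need >= 6 zinc concentrations spanning >= 2 log units")
  }
  ord <- order(x); x <- x[ord]; y <- y[ord]

  ## single-Hill inhibition
  single_resid <- function(th) y - .single_value(x, th)
  s_starts <- list(c(1, stats::median(x) * log(10), log(1.5)),
                   c(0.8, max(x) * log(10) - 1, log(1)),
                   c(1, log(10^stats::quantile(x, 0.75)), log(2.5)))
  s_best <- NULL
  for (s in s_starts) {
    f <- tryCatch(minpack.lm::nls.lm(
      par = s, fn = single_resid,
      lower = c(1e-6, min(x) * log(10) - 7, log(1e-2)),
      upper = c(1.2, max(x) * log(10) + 7, log(30)),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(f) && (is.null(s_best) || f$deviance < s_best$deviance)) s_best <- f
  }
  single <- if (!is.null(s_best)) {
    th <- unname(s_best$par)
    list(inhibition_amplitude = th[1], ic50_zn = exp(th[2]), n_h = exp(th[3]),
         rss = s_best$deviance, n_obs = length(x), n_par = 3L, theta = th)
  } else NULL

  ## biphasic: amplitudes + log c50s + log slopes
  bi_resid <- function(th) y - .biphasic_value(x, th)
  peak_x <- x[which.max(y)]
  b_starts <- list(
    c(max(max(y) - 1, 0.05), min(min(y) - 1, -0.05), peak_x * log(10) - 0.5,
      max(x) * log(10), log(1.5), log(1.5)),
    c(0.5, -1, stats::median(x) * log(10), max(x) * log(10) - 0.5, log(2), log(2)),
    c(0.05, -1, peak_x * log(10), stats::median(x) * log(10), log(1), log(1.5)),
    c(max(max(y) - 1, 0.05), -1.2, peak_x * log(10) - 1, max(x) * log(10) + 1,
      log(1.8), log(2.1))
  )
  lowerb <- c(0, -3, min(x) * log(10) - 7, min(x) * log(10) - 7, log(1e-2), log(1e-2))
  upperb <- c(5, 0, max(x) * log(10) + 7, max(x) * log(10) + 7, log(30), log(30))
  b_best <- NULL
  for (s in b_starts) {
    f <- tryCatch(minpack.lm::nls.lm(
      par = s, fn = bi_resid, lower = lowerb, upper = upperb,
      control = minpack.lm::nls.lm.control(maxiter = 1000)),
      error = function(e) NULL)
    if (!is.null(f) && (is.null(b_best) || f$deviance < b_best$deviance)) b_best <- f
  }
  biphasic <- if (!is.null(b_best)) {
    .biphasic_from_theta(unname(b_best$par), b_best$deviance, length(x))
  } else NULL

  if (is.null(single) && is.null(biphasic)) {
    stop("neither the single-Hill nor the biphasic model converged")
  }
  structure(list(biphasic = biphasic, single = single,
                 x = x, y = y, cell_id = curve$cell_id),
            class = "zinc_fit_pair")
}

#' Classify zinc modulation as biphasic or inhibition-only
#'
#' A curve is called biphasic only if (a) the biphasic model improves on
#' the nested single-Hill inhibition model by an extra-sum-of-squares F
#' test at level `alpha`, and (b) its fitted peak enhancement exceeds the
#' control response by more than `margin`.  Otherwise the modulation is
#' classified inhibition-only.  If only one model converged, the call is
#' made from that model and flagged low-confidence.
#'
#' @param fits a `zinc_fit_pair` from [fit_biphasic()].
#' @param alpha F-test significance level (default 0.05).
#' @param margin minimum fractional peak enhancement over control to call
#'   potentiation (default 0.10, i.e. +10%).
#' @return List of class `zinc_classification`: `class` (`"biphasic"` or
#'   `"inhibition_only"`), `peak_enhancement`, `f_statistic`, `p_value`,
#'   `low_confidence`, `zero_effect`.
#' @export
classify_modulation <- function(fits, alpha = 0.05, margin = 0.10) {
  stopifnot(inherits(fits, "zinc_fit_pair"))
  bi <- fits$biphasic; si <- fits$single
  low_conf <- is.null(bi) || is.null(si)
  zero_effect <- FALSE
  peak <- f_stat <- p_val <- NA_real_
  if (!is.null(bi)) {
    grid <- seq(min(fits$x) - 1, max(fits$x) + 1, length.out = 400)
    peak <- max(.biphasic_value(grid, bi$theta)) - 1
  }
  if (!is.null(bi) && !is.null(si)) {
    n <- bi$n_obs
    df2 <- n - bi$n_par
    df1 <- bi$n_par - si$n_par
    if (df2 > 0 && bi$rss > 0) {
      f_stat <- ((si$rss - bi$rss) / df1) / (bi$rss / df2)
      p_val <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
    } else {
      ## saturated/noiseless biphasic fit: fall back to RSS comparison
      f_stat <- Inf
      p_val <- if (si$rss > bi$rss + 1e-12) 0 else 1
    }
    cls <- if (!is.na(p_val) && p_val < alpha && peak > margin) {
      "biphasic"
    } else "inhibition_only"
  } else if (!is.null(bi)) {
    cls <- if (peak > margin) "biphasic" else "inhibition_only"
  } else {
    cls <- "inhibition_only"
  }
  if (cls == "inhibition_only") {
    amp <- if (!is.null(si)) si$inhibition_amplitude else NA_real_
    tot_var <- stats::var(fits$y)
    if (isTRUE(tot_var < 1e-10) ||
        (!is.null(si) && si$rss >= 0.999 * sum((fits$y - mean(fits$y))^2) &&
         isTRUE(abs(mean(fits$y) - 1) < 0.02))) {
      zero_effect <- TRUE
    }
  }
  structure(list(class = cls, peak_enhancement = peak,
                 f_statistic = f_stat, p_value = p_val,
                 low_confidence = low_conf, zero_effect = zero_effect),
            class = "zinc_classification")
}

#' @export
print.zinc_classification <- function(x, ...) {
  cat(sprintf("<zinc modulation: %s (peak enhancement %+.1f%%, F = %.3g, p = %.3g)%s%s>\n",
              x$class, 100 * x$peak_enhancement, x$f_statistic, x$p_value,
              if (x$low_confidence) " [low confidence]" else "",
              if (x$zero_effect) " [no detectable effect]" else ""))
  invisible(x)
}
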