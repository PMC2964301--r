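#' Construct a partial (foot-of-curve) dose-response set for one cell
#'
#' Low-concentration responses (2-3 points per agonist, each under ~10%
#' of the cell's maximum) to several agonists recorded in one cell, with
#' ACh as the standard agonist.  At these concentrations the Hill curve
#' is a power law, so potency ratios can be read off as horizontal shifts
#' between parallel lines in log-log coordinates.
#'
#' @param cell_id cell label.
#' @param points data frame with columns `agonist`, `concentration` (uM)
#'   and `response` (nA).
#' @param standard_agonist the reference agonist (default `"ACh"`); must
#'   be present among the points.
#' @return An object of class `partial_curve_set`.
#' @export
partial_curve_set <- function(cell_id, points, standard_agonist = "ACh") {
  req <- c("agonist", "concentration", "response")
  miss <- setdiff(req, names(points))
  if (length(miss)) stop("points missing column(s): ", paste(miss, collapse = ", "))
  if (!standard_agonist %in% points$agonist) {
    stop("cell '", cell_id, "' lacks the standard agonist '", standard_agonist, "'")
  }
  if (any(points$concentration <= 0)) stop("concentrations must be positive")
  structure(list(cell_id = as.character(cell_id),
                 points = points[, req],
                 standard_agonist = standard_agonist),
            class = "partial_curve_set")
}

## drop non-positive responses (cannot be log-transformed), with a count
.usable_points <- function(cell) {
  p <- cell$points
  n_drop <- sum(p$response <= 0)
  if (n_drop > 0) {
    message(n_drop, " non-positive response(s) excluded before log transform",
            " (cell '", cell$cell_id, "')")
    p <- p[p$response > 0, ]
  }
  p
}

#' Parallel power-law fit of one cell's partial curves
#'
#' Fits `log10(response) = c_a + s * log10(concentration)` jointly over
#' all agonists with one common slope `s` and per-agonist intercepts
#' `c_a` (equal weighting).  The horizontal shift of agonist `a` relative
#' to the standard is `(c_a - c_std)/s` log units; the potency ratio is
#' `10^shift` (how many-fold less agonist than standard achieves the same
#' response) and the dose ratio is its reciprocal.
#'
#' @param cell a [partial_curve_set()].
#' @param confidence confidence level for the Fieller intervals on the
#'   potency ratios (default 0.95).
#' @return A list of class `powerlaw_fit`: common slope and SE, per-agonist
#'   intercepts, shifts, potency and dose ratios, Fieller confidence
#'   intervals on the potency ratios, residual df.
#' @export
fit_parallel_powerlaw <- function(cell, confidence = 0.95) {
  stopifnot(inherits(cell, "partial_curve_set"))
  p <- .usable_points(cell)
  cnt <- table(p$agonist)
  thin <- names(cnt)[cnt < 2]
  if (length(thin)) {
    warning("agonist(s) with fewer than 2 usable points skipped: ",
            paste(thin, collapse = ", "), " (cell '", cell$cell_id, "')")
    p <- p[!p$agonist %in% thin, ]
  }
  if (length(unique(p$agonist)) < 2) {
    stop("parallel power-law fit needs >= 2 agonists with >= 2 points each")
  }
  if (!cell$standard_agonist %in% p$agonist) {
    stop("standard agonist was skipped for lack of points; cannot form ratios")
  }
  p$agonist <- factor(p$agonist)
  p$agonist <- stats::relevel(p$agonist, ref = cell$standard_agonist)
  lx <- log10(p$concentration); ly <- log10(p$response)
  fit <- stats::lm(ly ~ agonist + lx, data = data.frame(agonist = p$agonist, lx = lx))
  cf <- stats::coef(fit)
  V <- stats::vcov(fit)
  s <- cf[["lx"]]
  agonists <- levels(p$agonist)
  other <- agonists[-1]
  ## intercept differences c_a - c_std are the agonist dummy coefficients
  shift <- ci_lo <- ci_hi <- unbounded <- stats::setNames(
    rep(NA_real_, length(agonists)), agonists)
  shift[cell$standard_agonist] <- 0
  ci_lo[cell$standard_agonist] <- ci_hi[cell$standard_agonist] <- 1
  unbounded[] <- FALSE
  tval <- stats::qt(1 - (1 - confidence) / 2, df = stats::df.residual(fit))
  for (a in other) {
    co <- paste0("agonist", a)
    m <- cf[[co]]
    fl <- fieller_interval(m, s, V[co, co], V["lx", "lx"], V[co, "lx"], tval)
    shift[a] <- m / s
    ci_lo[a] <- 10^fl[["low"]]
    ci_hi[a] <- 10^fl[["high"]]
    unbounded[a] <- attr(fl, "unbounded")
  }
  structure(list(cell_id = cell$cell_id,
                 standard_agonist = cell$standard_agonist,
                 slope = s, slope_se = sqrt(V["lx", "lx"]),
                 shift = shift,
                 potency_ratio = 10^shift,
                 dose_ratio = 10^(-shift),
                 ci = cbind(low = ci_lo, high = ci_hi),
                 unbounded = unbounded,
                 df = stats::df.residual(fit),
                 n_points = nrow(p)),
            class = "powerlaw_fit")
}

#' Fieller confidence bounds for a ratio of jointly normal estimates
#'
#' Classical Fieller's-theorem interval for `numerator / denominator`
#' given the estimates' variances and covariance and a t multiplier.
#' When `g = t^2 var(den) / den^2 >= 1` the denominator is not
#' significantly different from zero and the interval is unbounded; this
#' is flagged, not raised as an error.
#'
#' @param num,den numerator and denominator estimates (`den != 0`).
#' @param var_num,var_den,cov variances and covariance of the estimates.
#' @param t_value the t (or z) multiplier for the desired confidence.
#' @return `c(low, high)` with attribute `unbounded` (logical).
#' @export
fieller_interval <- function(num, den, var_num, var_den, cov, t_value) {
  if (den == 0) stop("denominator estimate must be nonzero")
  rho <- num / den
  g <- t_value^2 * var_den / den^2
  if (g >= 1) {
    out <- c(low = -Inf, high = Inf)
    attr(out, "unbounded") <- TRUE
    return(out)
  }
  disc <- var_num - 2 * rho * cov + rho^2 * var_den -
    g * (var_num - cov^2 / max(var_den, .Machine$double.eps))
  disc <- max(disc, 0)
  half <- (t_value / abs(den)) * sqrt(disc)
  centre <- rho - g * cov / max(var_den, .Machine$double.eps)
  out <- c(low = (centre - half) / (1 - g), high = (centre + half) / (1 - g))
  attr(out, "unbounded") <- FALSE
  out
}

#' Per-agonist free slopes (parallelism check)
#'
#' Independent log-log regressions per agonist, reported to confirm that
#' the partial curves are close enough to parallel for the constrained
#' fit to be meaningful.  At concentrations far below the EC50 the
#' log-log slope tends to the Hill coefficient.
#'
#' @param cell a [partial_curve_set()].
#' @return Data frame with columns `agonist`, `slope`, `se`, `n`.
#' @export
fit_free_slopes <- function(cell) {
  stopifnot(inherits(cell, "partial_curve_set"))
  p <- .usable_points(cell)
  out <- lapply(split(p, p$agonist), function(d) {
    if (nrow(d) < 2) {
      warning("agonist '", d$agonist[1], "' skipped: fewer than 2 points")
      return(NULL)
    }
    f <- stats::lm(log10(response) ~ log10(concentration), data = d)
    se <- if (nrow(d) > 2) sqrt(stats::vcov(f)[2, 2]) else NA_real_
    data.frame(agonist = as.character(d$agonist[1]),
               slope = stats::coef(f)[[2]], se = se, n = nrow(d))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Pool per-cell potency ratios into an agonist potency table
#'
#' Averages each agonist's potency ratio across cells (unweighted mean
#' +/- SEM) and combines the per-cell Fieller intervals as their pooled
#' range.  Free-slope estimates are averaged the same way.
#'
#' @param cells list of [partial_curve_set()] objects.
#' @param confidence per-cell Fieller confidence level (default 0.95).
#' @return Data frame of class `potency_table` with columns `agonist`,
#'   `potency_ratio`, `sem`, `ci_low`, `ci_high`, `free_slope`,
#'   `free_slope_sem`, `n_cells`, `single_cell` (flag: SEM unavailable).
#' @export
pool_potency <- function(cells, confidence = 0.95) {
  stopifnot(length(cells) >= 1)
  fits <- lapply(cells, fit_parallel_powerlaw, confidence = confidence)
  slopes <- lapply(cells, fit_free_slopes)
  ratios <- list(); ci_l <- list(); ci_h <- list(); fslope <- list()
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    for (a in names(f$potency_ratio)) {
      if (is.na(f$potency_ratio[[a]])) next
      ratios[[a]] <- c(ratios[[a]], f$potency_ratio[[a]])
      ci_l[[a]] <- c(ci_l[[a]], f$ci[a, "low"])
      ci_h[[a]] <- c(ci_h[[a]], f$ci[a, "high"])
    }
    s <- slopes[[i]]
    for (j in seq_len(nrow(s))) {
      fslope[[s$agonist[j]]] <- c(fslope[[s$agonist[j]]], s$slope[j])
    }
  }
  agonists <- names(ratios)
  out <- data.frame(
    agonist = agonists,
    potency_ratio = vapply(ratios, mean, numeric(1)),
    sem = vapply(ratios, function(v) {
      if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_
    }, numeric(1)),
    ci_low = vapply(ci_l, min, numeric(1)),
    ci_high = vapply(ci_h, max, numeric(1)),
    free_slope = vapply(agonists, function(a) {
      v <- fslope[[a]]; if (is.null(v)) NA_real_ else mean(v)
    }, numeric(1)),
    free_slope_sem = vapply(agonists, function(a) {
      v <- fslope[[a]]
      if (is.null(v) || length(v) < 2) NA_real_ else stats::sd(v) / sqrt(length(v))
    }, numeric(1)),
    n_cells = vapply(ratios, length, integer(1)),
    row.names = NULL
  )
  out$single_cell <- out$n_cells < 2
  class(out) <- c("potency_table", "data.frame")
  out
}
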