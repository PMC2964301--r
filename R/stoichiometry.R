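#' Per-copy EC50 shift factor
#'
#' Under the unitary-shift model, each copy of the 9' reporter mutation
#' multiplies agonist potency by the same factor `r`, so a receptor
#' carrying `n` mutant copies shifts its EC50 by `r^n`-fold.  Given the
#' measured potency ratio of mutant vs wild type and an assumed copy
#' number, the per-copy factor is the `n`-th root of the ratio; an
#' accompanying interval is transformed endpointwise by the same
#' monotone map.
#'
#' @param potency_ratio mutant/wild-type potency ratio (> 0).
#' @param copies assumed number of mutant copies, one of 1, 2, 3.
#' @param interval optional `c(low, high)` interval for the ratio.
#' @return The per-copy factor `r`; if `interval` was supplied, with an
#'   `interval` attribute transformed by the same root.
#' @examples
#' per_copy_shift(5.13, 2)   # ~2.26
#' per_copy_shift(18.6, 3)   # ~2.65
#' @export
per_copy_shift <- function(potency_ratio, copies, interval = NULL) {
  if (!isTRUE(potency_ratio > 0)) stop("potency_ratio must be positive")
  if (!copies %in% c(1L, 2L, 3L)) stop("copies must be 1, 2 or 3")
  r <- potency_ratio^(1 / copies)
  if (!is.null(interval)) {
    stopifnot(length(interval) == 2, all(interval > 0))
    attr(r, "interval") <- sort(interval^(1 / copies))
  }
  r
}

#' Linear fit of log10 EC50 against mutant copy number
#'
#' The unitary-shift model predicts a straight line when log10 EC50 is
#' plotted against the number of mutant copies in the pentamer, with
#' slope `-log10(r)`.  Ordinary least squares with R-squared as the
#' goodness measure; the fitted EC50 at any copy number is
#' `10^(intercept + slope * copies)`.
#'
#' @param points data frame with columns `copies` (integer) and `ec50`
#'   (uM, positive); at least 3 points over at least 2 distinct copy
#'   numbers.
#' @return List of class `copy_line`: `slope`, `intercept`, `r_squared`,
#'   `r` (the implied per-copy factor `10^-slope`), and `predict`,
#'   a function of copy number.
#' @export
fit_copy_line <- function(points) {
  stopifnot(all(c("copies", "ec50") %in% names(points)), all(points$ec50 > 0))
  if (nrow(points) < 3 || length(unique(points$copies)) < 2) {
    stop("need >= 3 points with >= 2 distinct copy numbers")
  }
  fit <- stats::lm(log10(ec50) ~ copies, data = points)
  cf <- stats::coef(fit)
  structure(list(slope = cf[["copies"]],
                 intercept = cf[["(Intercept)"]],
                 r_squared = summary(fit)$r.squared,
                 r = 10^(-cf[["copies"]]),
                 n_points = nrow(points),
                 predict = function(copies) 10^(cf[[1]] + cf[[2]] * copies)),
            class = "copy_line")
}

#' @export
print.copy_line <- function(x, ...) {
  cat(sprintf("<copy_line: slope = %.4g (r = %.3g per copy), intercept = %.4g, R^2 = %.4f, n = %d>\n",
              x$slope, x$r, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Infer subunit stoichiometry from alpha- and beta-mutant potency ratios
#'
#' A pentamer holds either two or three copies of the alpha subunit
#' (with beta making up the remainder to five).  If each mutant copy
#' contributes the same per-copy potency factor `r`, then the assignment
#' under which the alpha-mutant and beta-mutant ratios imply the *same*
#' `r` is the plausible one.  Both candidate assignments,
#' (alpha, beta) = (2, 3) and (3, 2), are scored by the log-scale
#' discrepancy `|log r_alpha - log r_beta|` and the smaller wins; exact
#' ties (e.g. equal ratios) are flagged ambiguous.
#'
#' @param ratio_alpha_mutant potency ratio of the alpha-mutant receptor
#'   vs wild type (> 0).
#' @param ratio_beta_mutant potency ratio of the beta-mutant receptor
#'   vs wild type (> 0).
#' @param interval_alpha,interval_beta optional `c(low, high)` intervals
#'   for the two ratios; when supplied, assignment confidence is reported
#'   as non-overlap of the transformed per-copy intervals.
#' @return List of class `stoichiometry_fit`: chosen `assignment`
#'   (named vector alpha/beta copies), pooled `r`, per-candidate scores,
#'   `consistency_score`, `ambiguous` flag and, with intervals, the
#'   transformed intervals plus an `intervals_separate` confidence flag.
#' @examples
#' infer_stoichiometry(18.6, 5.13)  # three-alpha assignment
#' @export
infer_stoichiometry <- function(ratio_alpha_mutant, ratio_beta_mutant,
                                interval_alpha = NULL, interval_beta = NULL) {
  if (!isTRUE(ratio_alpha_mutant > 0) || !isTRUE(ratio_beta_mutant > 0)) {
    stop("both potency ratios must be positive")
  }
  candidates <- list(two_alpha = c(alpha = 2L, beta = 3L),
                     three_alpha = c(alpha = 3L, beta = 2L))
  score <- vapply(candidates, function(cn) {
    r_a <- per_copy_shift(ratio_alpha_mutant, cn[["alpha"]])
    r_b <- per_copy_shift(ratio_beta_mutant, cn[["beta"]])
    abs(log(r_a) - log(r_b))
  }, numeric(1))
  ambiguous <- isTRUE(all.equal(score[[1]], score[[2]]))
  pick <- if (ambiguous) NA_character_ else names(candidates)[which.min(score)]
  assignment <- if (ambiguous) NULL else candidates[[pick]]
  out <- list(assignment = assignment,
              label = pick,
              scores = score,
              consistency_score = min(score),
              ambiguous = ambiguous,
              ratios = c(alpha_mutant = ratio_alpha_mutant,
                         beta_mutant = ratio_beta_mutant))
  if (!ambiguous) {
    r_a <- per_copy_shift(ratio_alpha_mutant, assignment[["alpha"]],
                          interval = interval_alpha)
    r_b <- per_copy_shift(ratio_beta_mutant, assignment[["beta"]],
                          interval = interval_beta)
    out$r_alpha <- as.numeric(r_a)
    out$r_beta <- as.numeric(r_b)
    out$r <- exp(mean(log(c(out$r_alpha, out$r_beta))))
    if (!is.null(interval_alpha) && !is.null(interval_beta)) {
      ia <- attr(r_a, "interval"); ib <- attr(r_b, "interval")
      out$r_alpha_interval <- ia
      out$r_beta_interval <- ib
      ## confidence note: do the transformed per-copy intervals overlap?
      out$intervals_overlap <- ia[1] <= ib[2] && ib[1] <= ia[2]
    }
  }
  class(out) <- "stoichiometry_fit"
  out
}

#' @export
print.stoichiometry_fit <- function(x, ...) {
  if (x$ambiguous) {
    cat("<stoichiometry_fit: AMBIGUOUS (candidate scores equal)>\n")
  } else {
    cat(sprintf("<stoichiometry_fit: %s (alpha = %d, beta = %d), r_alpha = %.3g, r_beta = %.3g, consistency = %.3g>\n",
                x$label, x$assignment[["alpha"]], x$assignment[["beta"]],
                x$r_alpha, x$r_beta, x$consistency_score))
  }
  invisible(x)
}

#' Equal-efficacy EC50 extrapolation
#'
#' Converts a foot-of-curve potency ratio into a predicted full-curve
#' EC50, assuming the agonist matches the standard agonist's maximal
#' response: an agonist `p`-fold more potent than the standard is
#' predicted to have an EC50 of `reference_ec50 / p`.
#'
#' @param reference_ec50 the standard agonist's EC50 (uM, > 0).
#' @param potency_ratio the agonist's potency ratio vs standard (> 0).
#' @return Predicted EC50 in uM.
#' @examples
#' equal_efficacy_ec50(309, 10.2)   # ~30 uM
#' equal_efficacy_ec50(138, 0.99)   # ~140 uM
#' @export
equal_efficacy_ec50 <- function(reference_ec50, potency_ratio) {
  if (!isTRUE(reference_ec50 > 0) || !isTRUE(potency_ratio > 0)) {
    stop("reference_ec50 and potency_ratio must both be positive")
  }
  reference_ec50 / potency_ratio
}
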