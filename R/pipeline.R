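#' Run the full analysis pipeline
#'
#' Chains the analysis stages over whichever inputs are provided and
#' writes per-stage result tables plus a machine-readable JSON summary.
#' Stages with no applicable input are skipped with a logged warning,
#' not an error.
#'
#' Stages: (1) dose-response — rundown correction, per-cell Hill fits,
#' pooled-normalized parallel fit per receptor set against the `"wt"`
#' reference, and (if `alpha`/`beta` mutant sets are present) a
#' stoichiometry call from the potency ratios; (2) potency — per-cell
#' parallel power-law fits pooled into an agonist potency table;
#' (3) zinc — per-cell biphasic vs single-Hill fits and classification;
#' (4) single-channel — resolvable-amplitude filtering, amplitude
#' mixture, burst segmentation at `config$tcrit` and per-class burst
#' statistics.
#'
#' @param config an [analysis_config()].
#' @param inputs named list of file paths; recognized names:
#'   `dose_response`, `partial_curves`, `zinc`, `events`.
#' @param out_dir output directory (created if needed).
#' @return (Invisibly) a list with each stage's results and the summary.
#' @export
run_pipeline <- function(config, inputs, out_dir = ".") {
  stopifnot(inherits(config, "analysis_config"))
  known <- c("dose_response", "partial_curves", "zinc", "events")
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  if (length(inputs) == 0 || !any(names(inputs) %in% known)) {
    stop("at least one stage's inputs must be provided (",
         paste(known, collapse = ", "), ")")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$random_seed)
  log_lines <- c(sprintf("seed = %d", config$random_seed),
                 sprintf("R version = %s", getRversion()),
                 sprintf("pentafit version = %s",
                         as.character(utils::packageVersion("pentafit"))))
  results <- list()

  ## -- dose-response stage ------------------------------------------------
  if (!is.null(inputs$dose_response)) {
    cells <- read_dose_response_table(inputs$dose_response)
    cells <- lapply(cells, function(cl) {
      tryCatch(rundown_correct(cl), error = function(e) {
        warning("cell '", cl$cell_id, "': rundown correction skipped (",
                conditionMessage(e), ")")
        cl
      })
    })
    fits <- lapply(cells, fit_hill)
    hill_tab <- do.call(rbind, lapply(fits, function(f) {
      data.frame(cell_id = f$cell_id,
                 i_max = f$i_max %||% NA_real_,
                 ec50 = f$ec50 %||% NA_real_,
                 n_h = f$n_h %||% NA_real_,
                 se_i_max = if (is.null(f$se)) NA_real_ else f$se[["i_max"]],
                 se_ec50 = if (is.null(f$se)) NA_real_ else f$se[["ec50"]],
                 se_n_h = if (is.null(f$se)) NA_real_ else f$se[["n_h"]],
                 rss = f$rss %||% NA_real_,
                 n_points = f$n_points %||% NA_integer_,
                 converged = isTRUE(f$converged))
    }))
    rownames(hill_tab) <- NULL
    utils::write.table(hill_tab, file.path(out_dir, "hill_fits.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    results$hill_fits <- hill_tab
    for (f in fits) {
      if (isTRUE(f$converged)) {
        log_lines <- c(log_lines, sprintf(
          "hill_fit %s: i_max=%.8g ec50=%.8g n_h=%.8g rss=%.8g",
          f$cell_id, f$i_max, f$ec50, f$n_h, f$rss))
      }
    }

    receptors <- unique(vapply(cells, `[[`, character(1), "receptor"))
    receptors <- receptors[!is.na(receptors)]
    if (length(receptors) >= 2 && "wt" %in% receptors) {
      curves <- normalize_pool(cells, by = "receptor")
      pf <- parallel_fit(curves, reference = "wt",
                         likelihood_delta = config$likelihood_delta)
      par_tab <- data.frame(curve = pf$curve_names,
                            dose_ratio = pf$dose_ratios,
                            potency_ratio = pf$potency_ratios,
                            li_low = pf$likelihood_intervals[, "low"],
                            li_high = pf$likelihood_intervals[, "high"],
                            shared_n_h = pf$shared_n_h,
                            reference_ec50 = pf$reference_ec50)
      rownames(par_tab) <- NULL
      utils::write.table(par_tab, file.path(out_dir, "parallel_fit.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      results$parallel_fit <- pf
      log_lines <- c(log_lines, sprintf(
        "parallel_fit: shared_n_h=%.8g reference_ec50=%.8g rss=%.8g",
        pf$shared_n_h, pf$reference_ec50, pf$rss))

      if (all(c("alpha", "beta") %in% receptors)) {
        ## potency ratio of mutant vs wt = 1 / dose ratio
        st <- infer_stoichiometry(
          pf$potency_ratios[["alpha"]], pf$potency_ratios[["beta"]],
          interval_alpha = sort(1 / pf$likelihood_intervals["alpha", ]),
          interval_beta = sort(1 / pf$likelihood_intervals["beta", ]))
        st_tab <- data.frame(
          assignment = st$label %||% "ambiguous",
          alpha_copies = if (st$ambiguous) NA_integer_ else st$assignment[["alpha"]],
          beta_copies = if (st$ambiguous) NA_integer_ else st$assignment[["beta"]],
          r_alpha = st$r_alpha %||% NA_real_,
          r_beta = st$r_beta %||% NA_real_,
          consistency_score = st$consistency_score,
          score_two_alpha = st$scores[["two_alpha"]],
          score_three_alpha = st$scores[["three_alpha"]])
        utils::write.table(st_tab, file.path(out_dir, "stoichiometry.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        results$stoichiometry <- st
        log_lines <- c(log_lines, sprintf(
          "stoichiometry: %s (consistency=%.8g)", st_tab$assignment,
          st$consistency_score))
      }
    }
  } else {
    warning("dose-response stage skipped: no input")
    log_lines <- c(log_lines, "stage dose_response skipped (no input)")
  }

  ## -- potency stage ------------------------------------------------------
  if (!is.null(inputs$partial_curves)) {
    pcells <- read_partial_curve_table(inputs$partial_curves)
    pot <- pool_potency(pcells, confidence = config$fieller_confidence)
    utils::write.table(as.data.frame(pot), file.path(out_dir, "potency_table.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    results$potency <- pot
    log_lines <- c(log_lines, sprintf("potency: %d agonists pooled over %d cells",
                                      nrow(pot), length(pcells)))
  } else {
    warning("potency stage skipped: no input")
    log_lines <- c(log_lines, "stage potency skipped (no input)")
  }

  ## -- zinc stage ----------------------------------------------------------
  if (!is.null(inputs$zinc)) {
    zcurves <- read_zinc_table(inputs$zinc)
    ztab <- do.call(rbind, lapply(zcurves, function(z) {
      fp <- fit_biphasic(z)
      cl <- classify_modulation(fp)
      data.frame(cell_id = z$cell_id,
                 class = cl$class,
                 peak_enhancement = cl$peak_enhancement,
                 f_statistic = cl$f_statistic,
                 p_value = cl$p_value,
                 ec50_zn = if (is.null(fp$biphasic)) NA_real_ else fp$biphasic$ec50_zn,
                 ic50_zn_biphasic = if (is.null(fp$biphasic)) NA_real_ else fp$biphasic$ic50_zn,
                 ic50_zn_single = if (is.null(fp$single)) NA_real_ else fp$single$ic50_zn,
                 n_h_single = if (is.null(fp$single)) NA_real_ else fp$single$n_h)
    }))
    rownames(ztab) <- NULL
    utils::write.table(ztab, file.path(out_dir, "zinc_fits.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    results$zinc <- ztab
    log_lines <- c(log_lines, sprintf("zinc: %d curve(s), classes: %s",
                                      nrow(ztab), paste(ztab$class, collapse = ",")))
  } else {
    warning("zinc stage skipped: no input")
    log_lines <- c(log_lines, "stage zinc skipped (no input)")
  }

  ## -- single-channel stage -------------------------------------------------
  if (!is.null(inputs$events)) {
    rec <- read_event_table(inputs$events)
    resolvable <- filter_resolvable(rec)
    mix <- fit_amplitude_mixture(resolvable$amplitude_pA)
    bursts <- segment_bursts(rec, tcrit = config$tcrit)
    stats_tab <- burst_class_stats(bursts, mix,
                                   reversal_potential = config$reversal_potential)
    utils::write.table(mix$components, file.path(out_dir, "amplitude_mixture.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(as.data.frame(stats_tab),
                       file.path(out_dir, "burst_stats.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    results$single_channel <- list(mixture = mix, bursts = bursts,
                                   class_stats = stats_tab)
    log_lines <- c(log_lines, sprintf(
      "single_channel: %d components, %d bursts at tcrit=%g ms",
      mix$k, nrow(bursts$bursts), config$tcrit))
  } else {
    warning("single-channel stage skipped: no input")
    log_lines <- c(log_lines, "stage single_channel skipped (no input)")
  }

  summary <- list(
    seed = config$random_seed,
    stages_run = names(results),
    stoichiometry_call = if (!is.null(results$stoichiometry))
      results$stoichiometry$label else NULL,
    zinc_classes = if (!is.null(results$zinc)) results$zinc$class else NULL
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  results$summary <- summary
  invisible(results)
}

## null-default helper
`%||%` <- function(a, b) if (is.null(a)) b else a
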