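#' Read and write dose-response tables
#'
#' Tab-separated text with a header row and columns `cell_id`,
#' `application_index`, `agonist`, `concentration` (uM), `response`
#' (nA), `is_standard` (TRUE/FALSE) and optionally `receptor`.
#' `read_dose_response_table()` returns one [dose_response_cell()] per
#' cell, applications ordered by index; `write_dose_response_table()` is
#' its exact inverse (write-read round trips reproduce the numbers).
#'
#' @param path file path.
#' @return A named list of `dose_response_cell` objects.
#' @export
read_dose_response_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("cell_id", "application_index", "agonist", "concentration",
           "response", "is_standard")
  miss <- setdiff(req, names(d))
  if (length(miss)) {
    stop("dose-response table format error: missing column(s) ",
         paste(miss, collapse = ", "))
  }
  bad <- which(!(d$concentration > 0))
  if (length(bad)) {
    stop("validation error: non-positive concentration at row ", bad[1],
         " (cell '", d$cell_id[bad[1]], "')")
  }
  if (!"receptor" %in% names(d)) d$receptor <- NA_character_
  d$is_standard <- as.logical(d$is_standard)
  cells <- lapply(split(d, d$cell_id), function(dd) {
    dose_response_cell(dd$cell_id[1], dd, receptor = dd$receptor[1])
  })
  cells[order(names(cells))]
}

#' @rdname read_dose_response_table
#' @param cells list of `dose_response_cell` objects.
#' @export
write_dose_response_table <- function(cells, path) {
  rows <- lapply(cells, function(cl) {
    a <- cl$applications
    a$cell_id <- cl$cell_id
    a$receptor <- cl$receptor
    a
  })
  d <- do.call(rbind, rows)
  d <- d[, c("cell_id", "receptor", "application_index", "agonist",
             "concentration", "response", "is_standard")]
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write zinc modulation tables
#'
#' Tab-separated columns `cell_id`, `zinc_concentration` (uM),
#' `normalized_response`, and optionally `ach_concentration`.
#'
#' @param path file path.
#' @return Named list of [zinc_curve()] objects, one per cell.
#' @export
read_zinc_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("cell_id", "zinc_concentration", "normalized_response")
  miss <- setdiff(req, names(d))
  if (length(miss)) {
    stop("zinc table format error: missing column(s) ", paste(miss, collapse = ", "))
  }
  lapply(split(d, d$cell_id), function(dd) {
    zinc_curve(dd,
               ach_concentration = if ("ach_concentration" %in% names(dd))
                 dd$ach_concentration[1] else NA_real_,
               cell_id = dd$cell_id[1])
  })
}

#' @rdname read_zinc_table
#' @param curves named list of `zinc_curve` objects.
#' @export
write_zinc_table <- function(curves, path) {
  d <- do.call(rbind, lapply(curves, function(z) {
    p <- z$points
    p$cell_id <- z$cell_id
    p$ach_concentration <- z$ach_concentration
    p
  }))
  d <- d[, c("cell_id", "zinc_concentration", "normalized_response",
             "ach_concentration")]
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write idealized event lists
#'
#' Tab-separated columns `state` (open/shut), `duration_ms`,
#' `amplitude_pA` (empty for shut events), preceded by `#`-prefixed
#' metadata lines: `# holding_potential_mV`, `# filter_cutoff_kHz`,
#' `# resolution_us`.
#'
#' @param path file path.
#' @return An [idealized_record()].
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 10)
  meta <- hdr[startsWith(hdr, "#")]
  get_meta <- function(key, default) {
    ln <- grep(key, meta, value = TRUE)
    if (length(ln)) as.numeric(sub(".*=\\s*", "", ln[1])) else default
  }
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("state", "duration_ms", "amplitude_pA")
  miss <- setdiff(req, names(d))
  if (length(miss)) {
    stop("event table format error: missing column(s) ", paste(miss, collapse = ", "))
  }
  idealized_record(d,
                   holding_potential = get_meta("holding_potential_mV", -100),
                   filter_cutoff = get_meta("filter_cutoff_kHz", 1),
                   resolution = get_meta("resolution_us", 100))
}

#' @rdname read_event_table
#' @param record an `idealized_record`.
#' @export
write_event_table <- function(record, path) {
  stopifnot(inherits(record, "idealized_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# holding_potential_mV = %.10g", record$holding_potential),
    sprintf("# filter_cutoff_kHz = %.10g", record$filter_cutoff),
    sprintf("# resolution_us = %.10g", record$resolution)
  ), con)
  utils::write.table(record$events, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read and write partial-curve (potency) tables
#'
#' Tab-separated columns `cell_id`, `agonist`, `concentration` (uM),
#' `response` (nA); the standard agonist defaults to `"ACh"`.
#'
#' @param path file path.
#' @param standard_agonist reference agonist label.
#' @return Named list of [partial_curve_set()] objects.
#' @export
read_partial_curve_table <- function(path, standard_agonist = "ACh") {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("cell_id", "agonist", "concentration", "response")
  miss <- setdiff(req, names(d))
  if (length(miss)) {
    stop("partial-curve table format error: missing column(s) ",
         paste(miss, collapse = ", "))
  }
  lapply(split(d, d$cell_id), function(dd) {
    partial_curve_set(dd$cell_id[1], dd, standard_agonist = standard_agonist)
  })
}

#' @rdname read_partial_curve_table
#' @param cells named list of `partial_curve_set` objects.
#' @export
write_partial_curve_table <- function(cells, path) {
  d <- do.call(rbind, lapply(cells, function(cl) {
    p <- cl$points
    p$cell_id <- cl$cell_id
    p
  }))
  d <- d[, c("cell_id", "agonist", "concentration", "response")]
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
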