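## shared fixture builders; all data generated in code

## noiseless Hill-curve points
hill_points <- function(i_max, ec50, n_h, conc = ec50 * 10^seq(-1.5, 1.5, length.out = 8)) {
  data.frame(concentration = conc,
             response = i_max * conc^n_h / (conc^n_h + ec50^n_h))
}

## a dose_response_cell built from explicit vectors
make_cell <- function(id = "c1", conc, resp, std_conc = NULL, std_resp = NULL,
                      receptor = NA_character_) {
  n_t <- length(conc)
  if (is.null(std_conc)) {
    app <- data.frame(application_index = seq_len(n_t), agonist = "ACh",
                      concentration = conc, response = resp,
                      is_standard = FALSE)
  } else {
    ## standards interleaved: one before, one mid, one after
    n_s <- length(std_resp)
    std_idx <- round(seq(1, n_t + n_s, length.out = n_s))
    idx_all <- seq_len(n_t + n_s)
    is_std <- idx_all %in% std_idx
    conc_all <- resp_all <- numeric(n_t + n_s)
    conc_all[is_std] <- std_conc
    resp_all[is_std] <- std_resp
    conc_all[!is_std] <- conc
    resp_all[!is_std] <- resp
    app <- data.frame(application_index = idx_all,
                      agonist = ifelse(is_std, "ACh_std", "ACh"),
                      concentration = conc_all, response = resp_all,
                      is_standard = is_std)
  }
  dose_response_cell(id, app, receptor = receptor)
}

## the hand-enumerated 7-event toy record:
## open 1, shut 0.2, open 2, shut 8, open 1.5, shut 0.3, open 0.5 (ms)
toy_record <- function(resolution = 50, filter_cutoff = 1) {
  idealized_record(
    data.frame(state = c("open", "shut", "open", "shut", "open", "shut", "open"),
               duration_ms = c(1, 0.2, 2, 8, 1.5, 0.3, 0.5),
               amplitude_pA = c(2.5, NA, 2.7, NA, 3.8, NA, 4.0)),
    holding_potential = -100, filter_cutoff = filter_cutoff,
    resolution = resolution)
}
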