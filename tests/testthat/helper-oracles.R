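# Independent oracles and small builders shared across tests.

# Literal pairwise restatement of the sequential contamination rule,
# deliberately written as a plain loop, independent of the vectorized
# implementation it checks.
oracle_classify <- function(concs, lod) {
  out <- character(length(concs))
  for (k in seq_along(concs)) {
    detected_k <- concs[k] > 0 && concs[k] >= lod
    if (!detected_k) {
      out[k] <- "negative"
    } else if (k == 1) {
      out[k] <- "positive"
    } else {
      prev_detected <- concs[k - 1] > 0 && concs[k - 1] >= lod
      if (prev_detected && concs[k] <= concs[k - 1]) {
        out[k] <- "contaminated"
      } else {
        out[k] <- "positive"
      }
    }
  }
  out
}

# one-substance panel builder for simulator tests
one_substance_panel <- function(use_probability = 0.2, lod = 20,
                                conc_log_mean = 8.05, conc_log_sd = 1.7,
                                name = "acetazolamide") {
  substance_panel(data.frame(
    name = name, drug_class = "diuretics",
    use_probability = use_probability,
    conc_log_mean = conc_log_mean, conc_log_sd = conc_log_sd, lod = lod
  ))
}

# per-substance status tibble for one sample
one_sample_statuses <- function(...) {
  statuses <- c(...)
  tibble::tibble(
    site_id = "hut", cassette_id = "c1", slot = 1L,
    substance = names(statuses), status = unname(statuses),
    concentration_ng_ml = ifelse(statuses == "negative", 0, 100)
  )
}

# random per-substance status datasets for recount oracles
random_statuses <- function(n_samples, substances, seed) {
  withr::with_seed(seed, {
    tidyr::expand_grid(
      site_id = "hut", cassette_id = "c1", slot = seq_len(n_samples),
      substance = substances
    ) |>
      dplyr::mutate(
        status = sample(c("positive", "negative", "contaminated"),
                        dplyr::n(), replace = TRUE,
                        prob = c(0.25, 0.6, 0.15)),
        concentration_ng_ml = ifelse(.data$status == "negative", 0,
                                     stats::runif(dplyr::n(), 1, 1000))
      )
  })
}
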