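#' Build a substance panel
#'
#' A panel describes the substances an assay screens for, together with the
#' generative parameters the simulator needs: the per-visitor probability of
#' use, a log-normal urinary concentration model, and the reporting limit
#' below which a concentration is treated as not detected.
#'
#' @param substances A data frame with one row per substance and columns
#'   `name`, `drug_class`, `use_probability` (in `[0, 1]`),
#'   `conc_log_mean` (natural-log scale location, ng/ml),
#'   `conc_log_sd` (log-scale spread, `> 0`) and `lod`
#'   (reporting limit in ng/ml, `>= 0`).
#' @param metabolite_links A data frame with columns `primary` and
#'   `metabolite`, listing metabolites that are always detected together
#'   with their parent compound and therefore counted once under the parent
#'   name (e.g. prednisone/prednisolone). May have zero rows. Each
#'   metabolite may appear in at most one link.
#'
#' @return A tibble of class `substance_panel` with the substance table as
#'   rows and the links stored in the `metabolite_links` attribute.
#' @examples
#' panel <- substance_panel(
#'   data.frame(
#'     name = "acetazolamide", drug_class = "diuretics",
#'     use_probability = 0.2, conc_log_mean = 8, conc_log_sd = 1.7, lod = 20
#'   )
#' )
#' @export
substance_panel <- function(substances,
                            metabolite_links = data.frame(
                              primary = character(), metabolite = character()
                            )) {
  required <- c("name", "drug_class", "use_probability",
                "conc_log_mean", "conc_log_sd", "lod")
  missing_cols <- setdiff(required, names(substances))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("panel is missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "carryprev_config_error"
    )
  }
  substances <- tibble::as_tibble(substances)[required]
  if (anyDuplicated(substances$name)) {
    rlang::abort("substance names must be unique within a panel",
                 class = "carryprev_config_error")
  }
  check_field <- function(ok, field) {
    if (!all(ok)) {
      rlang::abort(
        paste0("invalid value in panel field '", field, "' for substance(s): ",
               paste(substances$name[!ok], collapse = ", ")),
        class = "carryprev_config_error"
      )
    }
  }
  check_field(substances$use_probability >= 0 & substances$use_probability <= 1,
              "use_probability")
  check_field(substances$conc_log_sd > 0, "conc_log_sd")
  check_field(substances$lod >= 0, "lod")

  metabolite_links <- tibble::as_tibble(metabolite_links)
  if (nrow(metabolite_links) > 0) {
    unknown <- setdiff(
      c(metabolite_links$primary, metabolite_links$metabolite),
      substances$name
    )
    if (length(unknown) > 0) {
      rlang::abort(
        paste0("metabolite link references unknown substance(s): ",
               paste(unknown, collapse = ", ")),
        class = "carryprev_config_error"
      )
    }
    if (anyDuplicated(metabolite_links$metabolite)) {
      rlang::abort("each metabolite may appear in at most one link",
                   class = "carryprev_config_error")
    }
  }
  structure(substances,
            metabolite_links = metabolite_links,
            class = c("substance_panel", class(substances)))
}

#' Metabolite links of a panel
#' @param panel A [substance_panel()].
#' @return A tibble with columns `primary` and `metabolite`.
#' @export
metabolite_links <- function(panel) {
  attr(panel, "metabolite_links")
}

#' Default screening panel
#'
#' A six-substance panel spanning the drug classes most relevant to
#' high-altitude climbers: the diuretics acetazolamide (altitude-illness
#' prophylaxis, by far the most prevalent substance in hut urinals) and
#' hydrochlorothiazide, the hypnotic zolpidem, the glucocorticoid prednisone,
#' the cannabinoid THC, and caffeine. Use probabilities reflect observed
#' hut prevalences; log-normal concentration parameters are calibrated so
#' that simulated positives span the observed min-max concentration ranges
#' (which cover three to four orders of magnitude for the diuretics);
#' reporting limits sit at the smallest observed positive concentration.
#' Caffeine carries a deliberately high reporting threshold: dietary intake
#' is ubiquitous, so the assay only reports heavy exposure.
#'
#' @return A [substance_panel()].
#' @export
default_panel <- function() {
  substance_panel(
    tibble::tribble(
      ~name,                 ~drug_class,     ~use_probability, ~conc_log_mean, ~conc_log_sd, ~lod,
      "acetazolamide",       "diuretics",     0.206,            8.05,           1.70,         20,
      "hydrochlorothiazide", "diuretics",     0.016,            5.30,           1.30,         4,
      "zolpidem",            "hypnotics",     0.084,            1.27,           1.20,         0.1,
      "prednisone",          "glucocorticoids", 0.019,          4.50,           0.75,         11,
      "THC",                 "cannabinoids",  0.038,            3.55,           0.50,         8,
      "caffeine",            "stimulants",    0.009,            8.94,           0.20,         5000
    )
  )
}
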