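#' Classify one substance's concentrations along a cassette
#'
#' The conservative sequential rule: within a cassette, a detected
#' concentration is labelled `contaminated` when it is less than or equal
#' to the concentration measured in the previous slot (a pattern consistent
#' with residual-volume carryover from that sample), and `positive`
#' otherwise; undetected concentrations are `negative`. The first slot of a
#' cassette can never be contaminated, because the tube is rinsed when the
#' cassette is replaced. The comparison always uses the previous slot's
#' measured value, whatever that slot's own status: a sample that exceeds
#' the previous measurement cannot be pure carryover. A detection after an
#' undetected slot is positive — there is nothing to carry over.
#'
#' @param concs Recorded concentrations (ng/ml), ordered by slot within one
#'   cassette. Values below the reporting limit must already be recorded
#'   as 0.
#' @param lod Reporting limit (ng/ml); concentrations below it (or equal to
#'   0) are treated as not detected.
#' @return Character vector of statuses (`"positive"`, `"negative"`,
#'   `"contaminated"`), one per slot.
#' @examples
#' classify_sequence(c(100, 50), lod = 10)   # positive, contaminated
#' classify_sequence(c(100, 100), lod = 10)  # tie counts as carryover
#' classify_sequence(c(100, 50, 60), lod = 10)
#' @export
classify_sequence <- function(concs, lod = 0) {
  if (any(concs < 0)) {
    rlang::abort("concentrations must be non-negative",
                 class = "carryprev_validation_error")
  }
  detected <- concs >= lod & concs > 0
  prev_conc <- dplyr::lag(concs, default = 0)
  prev_detected <- dplyr::lag(detected, default = FALSE)
  dplyr::case_when(
    !detected                            ~ "negative",
    prev_detected & concs <= prev_conc   ~ "contaminated",
    .default = "positive"
  )
}

#' Per-substance statuses for a dataset
#'
#' Applies [classify_sequence()] to every (cassette, substance) series of a
#' long-format dataset, using each substance's reporting limit from the
#' panel.
#'
#' @param samples Long-format tibble as produced by [simulate_study()] or
#'   [read_samples()]: columns `site_id`, `cassette_id`, `slot`,
#'   `substance`, `concentration_ng_ml`, and optionally `below_lod`.
#' @param panel A [substance_panel()] providing the reporting limits.
#' @return A tibble with one row per (sample, substance): `site_id`,
#'   `cassette_id`, `slot`, `substance`, `concentration_ng_ml`, `status`.
#' @export
classify_substances <- function(samples, panel) {
  unknown <- setdiff(unique(samples$substance), panel$name)
  if (length(unknown) > 0) {
    rlang::abort(paste0("substance(s) not in panel: ",
                        paste(unknown, collapse = ", ")),
                 class = "carryprev_config_error")
  }
  conc <- samples$concentration_ng_ml
  if ("below_lod" %in% names(samples)) {
    conc <- ifelse(samples$below_lod == 1, 0, conc)
  }
  samples |>
    dplyr::mutate(concentration_ng_ml = conc) |>
    dplyr::left_join(
      dplyr::select(tibble::as_tibble(panel), "name", "lod"),
      by = c(substance = "name")
    ) |>
    dplyr::group_by(.data$cassette_id, .data$substance) |>
    dplyr::arrange(.data$slot, .by_group = TRUE) |>
    dplyr::mutate(status = classify_sequence(.data$concentration_ng_ml,
                                             .data$lod[1])) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$site_id, .data$cassette_id, .data$slot, .data$substance) |>
    dplyr::select("site_id", "cassette_id", "slot", "substance",
                  "concentration_ng_ml", "status")
}

#' Whole-sample status
#'
#' A sample is `positive` when at least one substance is positive in it,
#' regardless of other substances possibly contaminating it; `negative`
#' when nothing was detected and nothing contaminated it; `contaminated`
#' otherwise (no positive substance, at least one contaminated one).
#'
#' @param statuses Per-substance statuses from [classify_substances()].
#' @return A tibble with one row per sample: `site_id`, `cassette_id`,
#'   `slot`, `status`.
#' @export
classify_samples <- function(statuses) {
  if (nrow(statuses) == 0) {
    rlang::abort("empty status set", class = "carryprev_validation_error")
  }
  statuses |>
    dplyr::summarise(
      status = dplyr::case_when(
        any(.data$status == "positive")     ~ "positive",
        any(.data$status == "contaminated") ~ "contaminated",
        .default = "negative"
      ),
      .by = c("site_id", "cassette_id", "slot")
    )
}

#' Fold co-detected metabolites into their parent compound
#'
#' Some metabolites are always detected together with their parent
#' (prednisone/prednisolone, codeine/morphine, metoprolol/metoprolol acid);
#' counting both would double-count one intake. When a linked pair is
#' positive in the same sample, only the parent is kept positive and the
#' metabolite is set to negative. A metabolite positive without its parent
#' passes through unchanged, as do all unlinked substances. The operation
#' is idempotent.
#'
#' @param statuses Per-substance statuses from [classify_substances()].
#' @param panel A [substance_panel()] whose metabolite links to apply.
#' @return `statuses` with folded metabolite rows.
#' @export
collapse_metabolites <- function(statuses, panel) {
  links <- metabolite_links(panel)
  if (is.null(links) || nrow(links) == 0) {
    return(statuses)
  }
  for (i in seq_len(nrow(links))) {
    prim <- links$primary[i]
    met <- links$metabolite[i]
    primary_pos <- statuses |>
      dplyr::filter(.data$substance == prim, .data$status == "positive") |>
      dplyr::select("site_id", "cassette_id", "slot")
    statuses <- statuses |>
      dplyr::left_join(dplyr::mutate(primary_pos, .fold = TRUE),
                       by = c("site_id", "cassette_id", "slot")) |>
      dplyr::mutate(
        status = ifelse(.data$substance == met & .data$status == "positive" &
                          !is.na(.data$.fold),
                        "negative", .data$status)
      ) |>
      dplyr::select(-".fold")
  }
  statuses
}
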