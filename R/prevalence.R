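#' Large-sample normal-approximation (Wald) confidence interval
#'
#' For a binomial proportion `p = n_positive / n_effective`, the two-sided
#' interval `p +/- z * sqrt(p (1 - p) / n_effective)` on the percent scale,
#' with bounds clipped to `[0, 100]`. `z` is the exact two-sided normal
#' quantile for the requested level (1.959964 at 95%).
#'
#' @param n_positive Number of positive samples.
#' @param n_effective Effective denominator (`>= 1`).
#' @param level Confidence level, default 0.95.
#' @return One-row tibble: `estimate_pct`, `low_pct`, `high_pct` (unrounded;
#'   round to one decimal for table display).
#' @examples
#' wald_ci(154, 430) # 35.8 (31.3-40.3)
#' @export
wald_ci <- function(n_positive, n_effective, level = 0.95) {
  if (any(n_effective < 1)) {
    rlang::abort("n_effective must be >= 1 (prevalence undefined when every sample is contaminated)",
                 class = "carryprev_undefined_estimate")
  }
  if (any(n_positive < 0) || any(n_positive > n_effective)) {
    rlang::abort("n_positive must lie in [0, n_effective]",
                 class = "carryprev_validation_error")
  }
  p <- n_positive / n_effective
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(p * (1 - p) / n_effective)
  tibble::tibble(
    estimate_pct = 100 * p,
    low_pct = pmax(0, 100 * (p - half)),
    high_pct = pmin(100, 100 * (p + half))
  )
}

#' Contamination-adjusted substance prevalence
#'
#' The adjusted prevalence of a substance is
#' `100 * n_positive / (n_total - n_contaminated)`: samples contaminated
#' for that substance are removed from the denominator because nothing can
#' be said about them — their detection is consistent with pure carryover.
#' The confidence interval is the Wald interval on the reduced denominator.
#'
#' @param statuses Per-substance statuses from [classify_substances()]
#'   (optionally after [collapse_metabolites()]).
#' @param substances Substances to estimate; default all present.
#' @param level Confidence level.
#' @return A tibble with one row per substance: `label`, `n_total`,
#'   `n_positive`, `n_contaminated`, `prevalence_pct`, `ci_low_pct`,
#'   `ci_high_pct`, `level`.
#' @export
substance_prevalence <- function(statuses, substances = NULL, level = 0.95) {
  present <- unique(statuses$substance)
  if (is.null(substances)) {
    substances <- present
  }
  unknown <- setdiff(substances, present)
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown substance(s): ", paste(unknown, collapse = ", ")),
                 class = "carryprev_unknown_substance")
  }
  statuses |>
    dplyr::filter(.data$substance %in% substances) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_positive = sum(.data$status == "positive"),
      n_contaminated = sum(.data$status == "contaminated"),
      .by = "substance"
    ) |>
    dplyr::rename(label = "substance") |>
    finish_estimate(level)
}

finish_estimate <- function(counts, level) {
  ci <- wald_ci(counts$n_positive, counts$n_total - counts$n_contaminated, level)
  counts |>
    dplyr::mutate(
      prevalence_pct = ci$estimate_pct,
      ci_low_pct = ci$low_pct,
      ci_high_pct = ci$high_pct,
      level = level
    )
}

#' Whole-sample positive / negative / contaminated shares
#'
#' Shares of the three whole-sample statuses over all analyzed samples.
#' Unlike [substance_prevalence()], no denominator adjustment applies:
#' the three shares partition the dataset and sum to 100% before rounding.
#'
#' @param sample_statuses Per-sample statuses from [classify_samples()].
#' @param level Confidence level.
#' @return A tibble with rows `positive`, `negative`, `contaminated`:
#'   `label`, `n_total`, `n`, `share_pct`, `ci_low_pct`, `ci_high_pct`,
#'   `level`.
#' @export
sample_status_rates <- function(sample_statuses, level = 0.95) {
  if (nrow(sample_statuses) == 0) {
    rlang::abort("empty dataset: shares undefined",
                 class = "carryprev_undefined_estimate")
  }
  n_total <- nrow(sample_statuses)
  tibble::tibble(label = c("positive", "negative", "contaminated")) |>
    dplyr::mutate(
      n_total = n_total,
      n = purrr::map_int(.data$label,
                         \(s) sum(sample_statuses$status == s))
    ) |>
    dplyr::mutate(
      share_pct = wald_ci(.data$n, .data$n_total, level)$estimate_pct,
      ci_low_pct = wald_ci(.data$n, .data$n_total, level)$low_pct,
      ci_high_pct = wald_ci(.data$n, .data$n_total, level)$high_pct,
      level = level
    )
}

#' Drug-class prevalence
#'
#' A sample is class-positive when at least one member substance is
#' positive (regardless of other members possibly contaminating it), and
#' class-contaminated when no member is positive and at least one is
#' contaminated. The adjusted-prevalence formula then applies as for a
#' single substance.
#'
#' @param statuses Per-substance statuses.
#' @param drug_classes Classes to estimate; default all classes in the panel.
#' @param panel A [substance_panel()] giving class membership.
#' @param level Confidence level.
#' @return A tibble shaped like [substance_prevalence()] output, one row
#'   per class.
#' @export
class_prevalence <- function(statuses, panel, drug_classes = NULL, level = 0.95) {
  if (is.null(drug_classes)) {
    drug_classes <- unique(panel$drug_class)
  }
  absent <- setdiff(drug_classes, panel$drug_class)
  if (length(absent) > 0) {
    rlang::abort(paste0("class(es) with no panel member: ",
                        paste(absent, collapse = ", ")),
                 class = "carryprev_config_error")
  }
  membership <- dplyr::select(tibble::as_tibble(panel), "name", "drug_class")
  purrr::map(drug_classes, function(cl) {
    members <- membership$name[membership$drug_class == cl]
    statuses |>
      dplyr::filter(.data$substance %in% members) |>
      dplyr::summarise(
        class_status = dplyr::case_when(
          any(.data$status == "positive")     ~ "positive",
          any(.data$status == "contaminated") ~ "contaminated",
          .default = "negative"
        ),
        .by = c("site_id", "cassette_id", "slot")
      ) |>
      dplyr::summarise(
        label = cl,
        n_total = dplyr::n(),
        n_positive = sum(.data$class_status == "positive"),
        n_contaminated = sum(.data$class_status == "contaminated")
      )
  }) |>
    dplyr::bind_rows() |>
    finish_estimate(level)
}

#' Drug combinations per sample
#'
#' Every sample positive for two or more substances (after metabolite
#' collapse) contributes one row key: its exact set of positive
#' substances. Counts are reported per site and pooled; pooled percentages
#' use the full unadjusted sample count.
#'
#' @param statuses Per-substance statuses, after [collapse_metabolites()].
#' @param n_total Denominator for percentages; default the number of
#'   distinct samples in `statuses`.
#' @return A tibble with one row per observed combination: `combination`
#'   (substances joined by `" + "`), `n_substances`, one count column per
#'   site, `n_pooled`, `pct_of_total`. Attribute `n_multi_samples` carries
#'   the grand total of multi-substance samples. Empty when no sample has
#'   two or more positives.
#' @export
combination_table <- function(statuses, n_total = NULL) {
  samples <- dplyr::distinct(statuses, .data$site_id, .data$cassette_id, .data$slot)
  if (is.null(n_total)) {
    n_total <- nrow(samples)
  }
  multi <- statuses |>
    dplyr::filter(.data$status == "positive") |>
    dplyr::summarise(
      combination = paste(sort(.data$substance), collapse = " + "),
      n_substances = dplyr::n(),
      .by = c("site_id", "cassette_id", "slot")
    ) |>
    dplyr::filter(.data$n_substances >= 2)
  out <- multi |>
    dplyr::count(.data$combination, .data$n_substances, .data$site_id) |>
    tidyr::pivot_wider(names_from = "site_id", values_from = "n",
                       values_fill = 0L) |>
    dplyr::mutate(
      n_pooled = rowSums(dplyr::pick(-c("combination", "n_substances"))),
      pct_of_total = 100 * .data$n_pooled / n_total
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_pooled), .data$combination)
  attr(out, "n_multi_samples") <- nrow(multi)
  attr(out, "n_total") <- n_total
  out
}

#' Share of samples positive for a combination of substance groups
#'
#' Counts the multi-substance samples whose positive set intersects every
#' one of the given groups (e.g. acetazolamide together with any hypnotic)
#' and expresses them as a percentage of the full sample count.
#'
#' @param combos Output of [combination_table()].
#' @param groups A list of character vectors of substance names; a
#'   combination matches when it contains at least one member of each group.
#' @param n_total Denominator; default the one stored by
#'   [combination_table()].
#' @return One-row tibble: `n_matching`, `n_total`, `pct_of_total`.
#' @export
combination_share <- function(combos, groups, n_total = NULL) {
  if (is.null(n_total)) {
    n_total <- attr(combos, "n_total")
  }
  sets <- strsplit(combos$combination, " + ", fixed = TRUE)
  hit <- purrr::map_lgl(sets, function(s) {
    all(purrr::map_lgl(groups, \(g) any(g %in% s)))
  })
  n_matching <- sum(combos$n_pooled[hit])
  tibble::tibble(
    n_matching = n_matching,
    n_total = n_total,
    pct_of_total = 100 * n_matching / n_total
  )
}

#' Concentration summary among positive samples
#'
#' Mean, SD, minimum and maximum of the recorded concentrations over the
#' samples positive for each substance. Contaminated and negative samples
#' are excluded: a contaminated concentration partly reflects the previous
#' sample. SD is `NA` when only one positive exists (tables print such
#' cells without dispersion).
#'
#' @param statuses Per-substance statuses with the `concentration_ng_ml`
#'   column, from [classify_substances()].
#' @param substances Substances to summarise; default all with at least one
#'   positive sample.
#' @return A tibble: `substance`, `n`, `mean`, `sd`, `min`, `max` (ng/ml).
#'   Substances with zero positives yield no row.
#' @export
concentration_summary <- function(statuses, substances = NULL) {
  pos <- dplyr::filter(statuses, .data$status == "positive")
  if (!is.null(substances)) {
    pos <- dplyr::filter(pos, .data$substance %in% substances)
  }
  if (nrow(pos) == 0) {
    return(tibble::tibble(substance = character(), n = integer(),
                          mean = double(), sd = double(),
                          min = double(), max = double()))
  }
  pos |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$concentration_ng_ml),
      sd = ifelse(dplyr::n() >= 2, stats::sd(.data$concentration_ng_ml), NA_real_),
      min = min(.data$concentration_ng_ml),
      max = max(.data$concentration_ng_ml),
      .by = "substance"
    ) |>
    dplyr::arrange(.data$substance)
}

#' Format prevalence estimates the way drug-screening tables print them
#'
#' Renders `"20.6 (16.5-24.7)"` style cells with one decimal, suppressing
#' the interval when only one positive sample exists (the estimate still
#' carries computed bounds; only the display drops them).
#'
#' @param estimates Output of [substance_prevalence()], [class_prevalence()]
#'   or [sample_status_rates()].
#' @param decimals Decimals to print, default 1.
#' @return The input with an additional character column `formatted`.
#' @export
format_prevalence <- function(estimates, decimals = 1) {
  pct <- if ("prevalence_pct" %in% names(estimates)) {
    estimates$prevalence_pct
  } else {
    estimates$share_pct
  }
  n_pos <- if ("n_positive" %in% names(estimates)) estimates$n_positive else estimates$n
  fmt <- function(x) formatC(round(x, decimals), format = "f", digits = decimals)
  estimates |>
    dplyr::mutate(
      formatted = ifelse(
        n_pos == 1,
        fmt(pct),
        paste0(fmt(pct), " (", fmt(estimates$ci_low_pct), "–",
               fmt(estimates$ci_high_pct), ")")
      )
    )
}
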