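#' Monte-Carlo recovery experiment for the adjusted prevalence estimator
#'
#' Simulates repeated studies, classifies each with the conservative
#' sequential rule, and compares three estimators of a substance's use
#' prevalence against the generative truth:
#' \describe{
#'   \item{adjusted}{the contamination-adjusted statistic —
#'     positives / (total − contaminated) — with its Wald interval;}
#'   \item{naive}{every detection counts as positive over the full
#'     denominator (no discarding), quantifying what carryover would do to
#'     an unadjusted analysis;}
#'   \item{oracle}{the latent true-use share, the sampling-only benchmark
#'     with zero structural bias.}
#' }
#' Replicate `r` (1-based) uses seed `config$seed + r - 1`, so partial
#' reruns reproduce exactly.
#'
#' @param config A [simulation_config()]; its seed is the first
#'   replicate's seed.
#' @param n_replicates Number of simulated studies (`>= 1`).
#' @param substance Substance whose prevalence is tracked; default the
#'   first panel substance.
#' @param estimators Subset of `c("adjusted", "naive", "oracle")`.
#' @param level Confidence level for all intervals.
#' @return An object of class `recovery_experiment`: a list with
#'   `replicates` (one row per replicate x estimator: estimate, CI bounds,
#'   truth, coverage indicator, contaminated share), `substance`,
#'   `true_pct`, `n_replicates`, `level`. Use [generics::tidy()] for
#'   per-estimator aggregates and [generics::glance()] for a one-row
#'   summary.
#' @export
run_recovery <- function(config, n_replicates,
                         substance = config$panel$name[1],
                         estimators = c("adjusted", "naive", "oracle"),
                         level = 0.95) {
  if (n_replicates < 1) {
    rlang::abort("n_replicates must be >= 1", class = "carryprev_config_error")
  }
  bad <- setdiff(estimators, c("adjusted", "naive", "oracle"))
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown estimator(s): ", paste(bad, collapse = ", ")),
                 class = "carryprev_config_error")
  }
  if (!substance %in% config$panel$name) {
    rlang::abort(paste0("substance not in panel: ", substance),
                 class = "carryprev_unknown_substance")
  }
  true_pct <- 100 * config$panel$use_probability[config$panel$name == substance]

  reps <- purrr::map(seq_len(n_replicates), function(r) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    sim <- simulate_study(cfg)
    sub_samples <- dplyr::filter(sim$samples, .data$substance == !!substance)
    n_total <- nrow(sub_samples)

    statuses <- classify_substances(sub_samples, config$panel)
    n_pos <- sum(statuses$status == "positive")
    n_con <- sum(statuses$status == "contaminated")
    n_det <- sum(sub_samples$below_lod == 0)
    n_true <- sum(dplyr::filter(sim$truth, .data$substance == !!substance)$true_use)

    est <- list(
      adjusted = wald_ci(n_pos, n_total - n_con, level),
      naive = wald_ci(n_det, n_total, level),
      oracle = wald_ci(n_true, n_total, level)
    )[estimators]
    dplyr::bind_rows(est, .id = "estimator") |>
      dplyr::mutate(
        replicate = r,
        true_pct = true_pct,
        covered = .data$low_pct <= true_pct & true_pct <= .data$high_pct,
        n_samples = n_total,
        n_contaminated = n_con,
        contaminated_share_pct = 100 * n_con / n_total
      )
  })

  structure(
    list(replicates = dplyr::bind_rows(reps),
         substance = substance, true_pct = true_pct,
         n_replicates = n_replicates, level = level,
         base_seed = config$seed),
    class = "recovery_experiment"
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-estimator aggregates of a recovery experiment
#'
#' Mean estimate, mean bias, RMSE and CI coverage across replicates, each
#' with its Monte-Carlo standard error.
#'
#' @param x A `recovery_experiment`.
#' @param ... Unused.
#' @return A tibble with one row per estimator.
#' @method tidy recovery_experiment
#' @export
tidy.recovery_experiment <- function(x, ...) {
  x$replicates |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      mean_estimate_pct = mean(.data$estimate_pct),
      mean_bias_pct = mean(.data$estimate_pct - .data$true_pct),
      mc_se_bias_pct = stats::sd(.data$estimate_pct) / sqrt(dplyr::n()),
      rmse_pct = sqrt(mean((.data$estimate_pct - .data$true_pct)^2)),
      coverage = mean(.data$covered),
      mc_se_coverage = sqrt(mean(.data$covered) * (1 - mean(.data$covered)) /
                              dplyr::n()),
      mean_contaminated_share_pct = mean(.data$contaminated_share_pct),
      .by = "estimator"
    ) |>
    dplyr::mutate(true_pct = x$true_pct, .after = "estimator")
}

#' One-row summary of a recovery experiment
#'
#' @param x A `recovery_experiment`.
#' @param ... Unused.
#' @return A one-row tibble focused on the adjusted estimator (when run).
#' @method glance recovery_experiment
#' @export
glance.recovery_experiment <- function(x, ...) {
  agg <- tidy(x)
  focus <- if ("adjusted" %in% agg$estimator) "adjusted" else agg$estimator[1]
  row <- dplyr::filter(agg, .data$estimator == focus)
  tibble::tibble(
    substance = x$substance,
    n_replicates = x$n_replicates,
    true_pct = x$true_pct,
    estimator = focus,
    mean_bias_pct = row$mean_bias_pct,
    rmse_pct = row$rmse_pct,
    coverage = row$coverage
  )
}

#' @export
print.recovery_experiment <- function(x, ...) {
  cat("Recovery experiment:", x$n_replicates, "replicates,",
      "substance", x$substance,
      sprintf("(true prevalence %.1f%%)\n", x$true_pct))
  print(tidy(x))
  invisible(x)
}

#' Sensitivity of the estimators over a parameter grid
#'
#' Re-runs [run_recovery()] at every point of a grid over the carryover
#' fraction, the tracked substance's reporting limit, and the visitor
#' redundancy, sharing the base seed across points (common random numbers)
#' so trends are not masked by Monte-Carlo noise.
#'
#' @param config Base [simulation_config()].
#' @param n_replicates Replicates per grid point.
#' @param carryover_fraction,lod,revisit_mean Vectors of values; the grid
#'   is their Cartesian product. `NULL` keeps the base config's value.
#' @param substance Tracked substance; default first in the panel.
#' @param level Confidence level.
#' @return A tibble: grid columns plus the [tidy()] aggregates per
#'   estimator at each point.
#' @export
sensitivity_grid <- function(config, n_replicates,
                             carryover_fraction = NULL, lod = NULL,
                             revisit_mean = NULL,
                             substance = config$panel$name[1],
                             level = 0.95) {
  grid <- tidyr::expand_grid(
    carryover_fraction = carryover_fraction %||%
      config$carryover$carryover_fraction,
    lod = lod %||% config$panel$lod[config$panel$name == substance],
    revisit_mean = revisit_mean %||% config$revisit_mean
  )
  if (nrow(grid) == 0) {
    rlang::abort("empty sensitivity grid", class = "carryprev_validation_error")
  }
  purrr::pmap(grid, function(carryover_fraction, lod, revisit_mean) {
    cfg <- config
    cfg$carryover$carryover_fraction <- carryover_fraction
    cfg$panel$lod[cfg$panel$name == substance] <- lod
    cfg$revisit_mean <- revisit_mean
    run_recovery(cfg, n_replicates, substance = substance, level = level) |>
      tidy() |>
      dplyr::mutate(carryover_fraction = carryover_fraction,
                    lod = lod, revisit_mean = revisit_mean,
                    .before = 1)
  }) |>
    dplyr::bind_rows()
}
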