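#' Carryover model of the automated sampler
#'
#' Between two draws, the intake tubing retains a residual volume of the
#' previous sample; when the next sample is drawn, that residue mixes into
#' it. The transferred fraction of the previous concentration is
#' `residual / (residual + sample volume)` unless overridden directly.
#' Defaults reflect the field device: up to 4 ml retained against an
#' average drawn volume of 67 ml, i.e. a carryover fraction of about 5.6%.
#' The tubing is rinsed when a cassette is replaced, so carryover acts only
#' between consecutive slots of the same cassette.
#'
#' @param residual_volume_ml Residual liquid retained in the tube (ml).
#' @param sample_volume_ml Mean drawn sample volume (ml).
#' @param carryover_fraction Fraction of the previous measured concentration
#'   transferred into the next sample, in `[0, 1)`. Defaults to
#'   `residual_volume_ml / (residual_volume_ml + sample_volume_ml)`.
#' @return A list of class `carryover_model`.
#' @examples
#' carryover_model()$carryover_fraction # ~0.056
#' carryover_model(carryover_fraction = 0)
#' @export
carryover_model <- function(residual_volume_ml = 4,
                            sample_volume_ml = 67,
                            carryover_fraction = NULL) {
  if (residual_volume_ml < 0 || sample_volume_ml <= 0) {
    rlang::abort("volumes must be non-negative (sample volume positive): residual_volume_ml / sample_volume_ml",
                 class = "carryprev_config_error")
  }
  if (is.null(carryover_fraction)) {
    carryover_fraction <- residual_volume_ml / (residual_volume_ml + sample_volume_ml)
  }
  if (carryover_fraction < 0 || carryover_fraction >= 1) {
    rlang::abort("carryover_fraction must be in [0, 1)",
                 class = "carryprev_config_error")
  }
  structure(
    list(residual_volume_ml = residual_volume_ml,
         sample_volume_ml = sample_volume_ml,
         carryover_fraction = carryover_fraction),
    class = "carryover_model"
  )
}

#' Configuration of a simulated sampling study
#'
#' Describes the study the simulator generates: which substances are in
#' play, how many sampler-nights (cassettes) ran at each site, how many
#' urination events fell into each cassette, how often the same anonymous
#' visitor contributes more than one sample, and the carryover model.
#' Defaults emulate a two-hut field study: 21 + 14 sampler-nights with a
#' Poisson(12.3) number of events per night, roughly 430 samples in all.
#'
#' @param panel A [substance_panel()].
#' @param sites Named integer vector: number of cassettes per site, e.g.
#'   `c(gouter = 21, cosmiques = 14)`.
#' @param slots_per_cassette Capacity of one cassette (the sampler stops
#'   after this many draws); default 24.
#' @param events_per_cassette Either `"fill"` (every cassette fills all its
#'   slots), a single fixed integer, or `list(type = "poisson", mean = m)`
#'   for a Poisson count truncated to `[1, slots_per_cassette]`.
#' @param revisit_mean Expected number of samples contributed per visitor
#'   (`>= 1`). A visitor contributes `1 + Geometric` extra samples, placed
#'   in consecutive cassettes at the same site; default 1 (no redundancy).
#' @param carryover A [carryover_model()].
#' @param seed Integer seed fixing the full output.
#' @return A list of class `simulation_config`.
#' @examples
#' cfg <- simulation_config(seed = 1)
#' @export
simulation_config <- function(panel = default_panel(),
                              sites = c(gouter = 21, cosmiques = 14),
                              slots_per_cassette = 24,
                              events_per_cassette = list(type = "poisson", mean = 12.3),
                              revisit_mean = 1,
                              carryover = carryover_model(),
                              seed) {
  if (missing(seed)) {
    rlang::abort("seed is mandatory in a simulation config",
                 class = "carryprev_config_error")
  }
  if (!inherits(panel, "substance_panel")) {
    rlang::abort("panel must be a substance_panel", class = "carryprev_config_error")
  }
  if (is.null(names(sites)) || any(!nzchar(names(sites)))) {
    rlang::abort("sites must be a named vector of cassette counts",
                 class = "carryprev_config_error")
  }
  if (any(sites < 1)) {
    rlang::abort("every site needs at least one cassette: sites",
                 class = "carryprev_config_error")
  }
  if (slots_per_cassette < 1) {
    rlang::abort("slots_per_cassette must be >= 1", class = "carryprev_config_error")
  }
  if (revisit_mean < 1) {
    rlang::abort("revisit_mean must be >= 1", class = "carryprev_config_error")
  }
  if (is.numeric(events_per_cassette) && length(events_per_cassette) == 1) {
    events_per_cassette <- list(type = "fixed", n = as.integer(events_per_cassette))
  } else if (identical(events_per_cassette, "fill")) {
    events_per_cassette <- list(type = "fixed", n = as.integer(slots_per_cassette))
  }
  if (!is.list(events_per_cassette) ||
      !events_per_cassette$type %in% c("fixed", "poisson")) {
    rlang::abort("events_per_cassette must be 'fill', a count, or list(type = 'poisson', mean = m)",
                 class = "carryprev_config_error")
  }
  if (events_per_cassette$type == "fixed" &&
      (events_per_cassette$n < 1 || events_per_cassette$n > slots_per_cassette)) {
    rlang::abort("fixed events_per_cassette must lie in [1, slots_per_cassette]: events_per_cassette",
                 class = "carryprev_config_error")
  }
  if (events_per_cassette$type == "poisson" &&
      (is.null(events_per_cassette$mean) || events_per_cassette$mean <= 0)) {
    rlang::abort("poisson events_per_cassette needs a positive mean: events_per_cassette",
                 class = "carryprev_config_error")
  }
  if (!inherits(carryover, "carryover_model")) {
    rlang::abort("carryover must be a carryover_model", class = "carryprev_config_error")
  }
  structure(
    list(panel = panel, sites = sites,
         slots_per_cassette = as.integer(slots_per_cassette),
         events_per_cassette = events_per_cassette,
         revisit_mean = revisit_mean, carryover = carryover,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# number of events for each cassette, truncated to [1, slots]
draw_event_counts <- function(spec, n_cassettes, slots) {
  if (spec$type == "fixed") {
    rep(spec$n, n_cassettes)
  } else {
    pmin(pmax(stats::rpois(n_cassettes, spec$mean), 1L), slots)
  }
}

#' Simulate a sampling study
#'
#' Generates one event-level dataset with the structure the analysis
#' assumes: each urination event comes from a (possibly returning)
#' anonymous visitor with latent per-substance use flags; a user's urine
#' concentration is a fresh log-normal draw at each visit; within a
#' cassette, each measured concentration is the true concentration plus
#' `carryover_fraction` times the previous slot's measured concentration
#' (slot 1 of every cassette starts clean — the tube is rinsed between
#' cassettes); measurements below the substance's reporting limit are
#' recorded as 0 with a `below_lod` flag.
#'
#' @param config A [simulation_config()].
#' @return A list with two tibbles:
#'   \describe{
#'     \item{samples}{long format, one row per (sample, substance):
#'       `site_id`, `cassette_id`, `slot`, `timestamp`, `substance`,
#'       `concentration_ng_ml` (recorded, 0 when not detected),
#'       `below_lod` (0/1).}
#'     \item{truth}{parallel latent truth: `site_id`, `cassette_id`,
#'       `slot`, `visitor_id`, `substance`, `true_use` (0/1),
#'       `true_conc_ng_ml` (pre-carryover).}
#'   }
#' @examples
#' sim <- simulate_study(simulation_config(seed = 42))
#' head(sim$samples)
#' @export
simulate_study <- function(config) {
  if (!inherits(config, "simulation_config")) {
    rlang::abort("config must be a simulation_config", class = "carryprev_config_error")
  }
  withr::with_seed(config$seed, simulate_study_impl(config))
}

simulate_study_impl <- function(config) {
  panel <- config$panel
  n_sub <- nrow(panel)
  visitor_counter <- 0L
  site_results <- vector("list", length(config$sites))

  for (si in seq_along(config$sites)) {
    site <- names(config$sites)[si]
    n_cas <- config$sites[[si]]
    events <- draw_event_counts(config$events_per_cassette, n_cas,
                                config$slots_per_cassette)
    # visitors scheduled to return on a later cassette keep their use flags
    pending <- vector("list", n_cas + 1L)
    cassette_results <- vector("list", n_cas)

    for (ci in seq_len(n_cas)) {
      n_ev <- events[ci]
      ids <- integer(n_ev)
      flags <- matrix(FALSE, n_ev, n_sub)
      queue <- pending[[ci]]
      n_ret <- min(length(queue), n_ev)
      if (n_ret > 0) {
        for (j in seq_len(n_ret)) {
          ids[j] <- queue[[j]]$id
          flags[j, ] <- queue[[j]]$use
        }
        leftover <- queue[-seq_len(n_ret)]
        if (length(leftover) > 0 && ci < n_cas) {
          pending[[ci + 1L]] <- c(pending[[ci + 1L]], leftover)
        }
      } else if (length(queue) > 0 && ci < n_cas) {
        pending[[ci + 1L]] <- c(pending[[ci + 1L]], queue)
      }
      if (n_ev > n_ret) {
        for (j in seq((n_ret + 1L), n_ev)) {
          visitor_counter <- visitor_counter + 1L
          use <- stats::runif(n_sub) < panel$use_probability
          ids[j] <- visitor_counter
          flags[j, ] <- use
          extra <- if (config$revisit_mean > 1) {
            stats::rgeom(1L, prob = 1 / config$revisit_mean)
          } else 0L
          if (extra > 0) {
            for (k in seq_len(extra)) {
              tgt <- ci + k
              if (tgt <= n_cas) {
                pending[[tgt]] <- c(pending[[tgt]],
                                    list(list(id = visitor_counter, use = use)))
              }
            }
          }
        }
      }

      # fresh concentration draw per visit for used substances
      true_conc <- matrix(0, n_ev, n_sub)
      for (s in seq_len(n_sub)) {
        users <- which(flags[, s])
        if (length(users) > 0) {
          true_conc[users, s] <- stats::rlnorm(length(users),
                                               panel$conc_log_mean[s],
                                               panel$conc_log_sd[s])
        }
      }
      # recursive carryover chain down the cassette, per substance
      f <- config$carryover$carryover_fraction
      measured <- true_conc
      if (f > 0 && n_ev > 1) {
        for (s in seq_len(n_sub)) {
          measured[, s] <- as.numeric(
            stats::filter(true_conc[, s], f, method = "recursive")
          )
        }
      }

      # event times within the night, sorted
      secs <- sort(stats::runif(n_ev, 0, 4 * 3600))
      night0 <- as.POSIXct("2013-07-15 00:00:00", tz = "UTC")
      stamps <- format(night0 + (ci - 1L) * 86400 + secs,
                       "%Y-%m-%dT%H:%M:%SZ")

      cassette_results[[ci]] <- list(
        cassette_id = sprintf("%s-c%03d", site, ci),
        slot = seq_len(n_ev), timestamp = stamps,
        visitor_id = ids, flags = flags,
        true_conc = true_conc, measured = measured
      )
    }
    site_results[[si]] <- list(site = site, cassettes = cassette_results)
  }

  # flatten to long tibbles
  rows <- purrr::map(site_results, function(sr) {
    purrr::map(sr$cassettes, function(cr) {
      n_ev <- length(cr$slot)
      detected <- sweep(cr$measured, 2, panel$lod, ">=") & cr$measured > 0
      tibble::tibble(
        site_id = sr$site,
        cassette_id = cr$cassette_id,
        slot = rep(cr$slot, times = n_sub),
        timestamp = rep(cr$timestamp, times = n_sub),
        visitor_id = rep(cr$visitor_id, times = n_sub),
        substance = rep(panel$name, each = n_ev),
        true_use = as.integer(as.vector(cr$flags)),
        true_conc_ng_ml = as.vector(cr$true_conc),
        measured = as.vector(cr$measured),
        detected = as.vector(detected)
      )
    })
  })
  long <- dplyr::bind_rows(purrr::flatten(rows))
  samples <- long |>
    dplyr::transmute(
      .data$site_id, .data$cassette_id, .data$slot, .data$timestamp,
      .data$substance,
      concentration_ng_ml = ifelse(.data$detected, .data$measured, 0),
      below_lod = as.integer(!.data$detected)
    )
  truth <- long |>
    dplyr::select("site_id", "cassette_id", "slot", "visitor_id",
                  "substance", "true_use", "true_conc_ng_ml")
  list(samples = samples, truth = truth)
}

#' Emulate the two-sample titration experiment
#'
#' In the field, the carryover rate was assessed by drawing a drug-titrated
#' urine sample followed by a blank one and checking whether the drug was
#' detected in the blank. This emulates that design: for each pair, the
#' blank's concentration is `carryover_fraction * titrated_conc`, and the
#' pair counts as contaminated when that meets the reporting limit.
#'
#' @param carryover A [carryover_model()]; its `carryover_fraction` is used
#'   for every pair unless `fraction_sampler` is given.
#' @param titrated_conc Concentration of the titrated first sample (ng/ml, > 0).
#' @param lod Reporting limit applied to the blank follow-up (ng/ml).
#' @param n_pairs Number of titrated/blank pairs.
#' @param seed Seed (only consulted when `fraction_sampler` is stochastic).
#' @param fraction_sampler Optional `function(n)` returning `n` random
#'   carryover fractions, for stochastic carryover; overrides the model's
#'   fixed fraction.
#' @return The observed carryover rate: fraction of blanks with a detected
#'   concentration. With a fixed fraction the result is exactly 0 or 1.
#' @examples
#' simulate_titration(carryover_model(carryover_fraction = 0), 1000, 10, 100, 1)
#' @export
simulate_titration <- function(carryover, titrated_conc, lod, n_pairs,
                               seed = 1L, fraction_sampler = NULL) {
  if (!inherits(carryover, "carryover_model")) {
    rlang::abort("carryover must be a carryover_model", class = "carryprev_config_error")
  }
  if (titrated_conc <= 0) {
    rlang::abort("titrated_conc must be positive", class = "carryprev_config_error")
  }
  if (n_pairs < 1) {
    rlang::abort("n_pairs must be >= 1", class = "carryprev_config_error")
  }
  fractions <- if (is.null(fraction_sampler)) {
    rep(carryover$carryover_fraction, n_pairs)
  } else {
    withr::with_seed(seed, fraction_sampler(n_pairs))
  }
  carried <- fractions * titrated_conc
  mean(carried >= lod & carried > 0)
}
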