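#' Read a long-format sample dataset
#'
#' Reads the one CSV dialect the pipeline speaks: UTF-8, comma-separated,
#' mandatory header, one row per (sample, substance) with columns
#' `site_id`, `cassette_id`, `slot`, `timestamp`, `substance`,
#' `concentration_ng_ml` and optionally `below_lod` (0/1). The same schema
#' serves simulated and real data.
#'
#' @param path CSV file path.
#' @return A validated tibble of sample records.
#' @export
read_samples <- function(path) {
  samples <- readr::read_csv(path, show_col_types = FALSE,
                             col_types = readr::cols(timestamp = "c"))
  validate_samples(samples)
}

#' Validate a sample dataset
#'
#' Checks the long-format invariants: required columns present, slots at
#' least 1, concentrations non-negative, and no duplicated
#' (cassette, slot, substance) record. Errors name the offending rows.
#'
#' @param samples A data frame of sample records.
#' @return The input as a tibble, invisibly validated.
#' @export
validate_samples <- function(samples) {
  required <- c("site_id", "cassette_id", "slot", "timestamp",
                "substance", "concentration_ng_ml")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("missing column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "carryprev_validation_error")
  }
  bad_slot <- which(samples$slot < 1)
  if (length(bad_slot) > 0) {
    rlang::abort(paste0("slot must be >= 1; offending row(s): ",
                        paste(utils::head(bad_slot, 5), collapse = ", ")),
                 class = "carryprev_validation_error")
  }
  bad_conc <- which(samples$concentration_ng_ml < 0)
  if (length(bad_conc) > 0) {
    rlang::abort(paste0("negative concentration; offending row(s): ",
                        paste(utils::head(bad_conc, 5), collapse = ", ")),
                 class = "carryprev_validation_error")
  }
  key <- paste(samples$cassette_id, samples$slot, samples$substance, sep = "\r")
  dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
  if (length(dup) > 0) {
    rlang::abort(paste0("duplicated (cassette_id, slot, substance); offending row(s): ",
                        paste(utils::head(dup, 10), collapse = ", ")),
                 class = "carryprev_validation_error")
  }
  tibble::as_tibble(samples)
}

#' Write a sample dataset
#'
#' @param samples Tibble of sample records (see [read_samples()] for the
#'   schema).
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  readr::write_csv(samples, path)
  invisible(path)
}

fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "carryprev")
  if (!nzchar(path)) {
    rlang::abort(paste0("packaged fixture not found: ", file),
                 class = "carryprev_validation_error")
  }
  path
}

check_fixture <- function(path, md5) {
  actual <- unname(tools::md5sum(path))
  if (!identical(actual, md5)) {
    rlang::abort(paste0("fixture checksum mismatch for ", basename(path),
                        ": ", actual),
                 class = "carryprev_validation_error")
  }
  path
}

# md5 sums of the shipped fixture CSVs; loading refuses silently altered files
TABLE1_MD5 <- "d408cf7456a7f12bd4b1bb34e3c2d441"
TABLE2_MD5 <- "61f05dc588d99c67f34325fca33d97e4"

#' Published per-substance prevalence and concentration table (fixture)
#'
#' The printed prevalence table of the two-hut field study, transcribed as
#' data: per-substance (and per-class) positive-sample percentages per hut
#' and pooled, pooled Wald CI bounds, and concentration summaries
#' (mean, SD, min, max in ng/ml; single-positive cells have no SD).
#' `metabolite_of` marks metabolites that were always co-detected with
#' their parent compound. Loading verifies an md5 checksum.
#'
#' @param verify Check the file checksum before loading (default `TRUE`).
#' @return A tibble, one row per printed table row.
#' @export
table1_fixture <- function(verify = TRUE) {
  path <- fixture_path("table1_prevalence.csv")
  if (verify) check_fixture(path, TABLE1_MD5)
  readr::read_csv(path, show_col_types = FALSE)
}

#' Published drug-combination table (fixture)
#'
#' The printed table of samples positive for two or three substances:
#' one row per combination with per-hut case counts. (One further sample
#' containing five substances was reported outside the table and is not
#' part of this fixture.) Loading verifies an md5 checksum.
#'
#' @param verify Check the file checksum before loading (default `TRUE`).
#' @return A tibble with columns `substance_1`, `substance_2`,
#'   `substance_3` (may be `NA`), `gouter`, `cosmiques`.
#' @export
table2_fixture <- function(verify = TRUE) {
  path <- fixture_path("table2_combinations.csv")
  if (verify) check_fixture(path, TABLE2_MD5)
  readr::read_csv(path, show_col_types = FALSE)
}

#' Expand the combination fixture into per-sample positive statuses
#'
#' Turns each fixture row into that many synthetic sample records per hut,
#' each positive for exactly the row's substances, so that
#' [combination_table()] can be run against the published counts.
#'
#' @param fixture Output of [table2_fixture()].
#' @return A per-substance status tibble (columns as
#'   [classify_substances()] output, minus concentrations).
#' @export
table2_samples <- function(fixture = table2_fixture()) {
  long <- fixture |>
    dplyr::mutate(combo_id = dplyr::row_number()) |>
    tidyr::pivot_longer(c("gouter", "cosmiques"),
                        names_to = "site_id", values_to = "n_cases") |>
    dplyr::filter(.data$n_cases > 0) |>
    tidyr::uncount(.data$n_cases, .id = "case") |>
    dplyr::mutate(sample_key = paste(.data$site_id, .data$combo_id,
                                     .data$case, sep = "-")) |>
    tidyr::pivot_longer(c("substance_1", "substance_2", "substance_3"),
                        values_to = "substance") |>
    dplyr::filter(!is.na(.data$substance))
  long |>
    dplyr::mutate(
      cassette_id = paste0(.data$site_id, "-t2"),
      slot = match(.data$sample_key, unique(.data$sample_key)),
      status = "positive"
    ) |>
    dplyr::select("site_id", "cassette_id", "slot", "substance", "status")
}
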