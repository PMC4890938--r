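test_that("Wald interval reproduces closed-form and boundary cases", {
  ci <- wald_ci(154, 430)
  expect_equal(round(ci$estimate_pct, 1), 35.8)
  expect_equal(round(ci$low_pct, 1), 31.3)
  expect_equal(round(ci$high_pct, 1), 40.3)
  # independent closed-form evaluation at a second point
  p <- 66 / 430
  half <- stats::qnorm(0.975) * sqrt(p * (1 - p) / 430)
  ci2 <- wald_ci(66, 430)
  expect_equal(ci2$low_pct, 100 * (p - half))
  expect_equal(round(ci2$low_pct, 1), 11.9)
  # degenerate proportion clips to zero width
  ci0 <- wald_ci(0, 100)
  expect_equal(c(ci0$low_pct, ci0$high_pct), c(0, 0))
  expect_error(wald_ci(3, 0), class = "carryprev_undefined_estimate")
  expect_error(wald_ci(5, 4), class = "carryprev_validation_error")
})

test_that("adjusted prevalence removes contaminated samples from the denominator", {
  st <- tibble::tibble(
    site_id = "hut", cassette_id = "c1", slot = 1:10,
    substance = "drugX",
    concentration_ng_ml = 50,
    status = rep(c("positive", "contaminated", "negative"), c(2, 2, 6))
  )
  est <- substance_prevalence(st)
  expect_equal(est$prevalence_pct, 25) # 2 / (10 - 2) x 100
  expect_equal(est$n_total, 10)
  expect_equal(est$n_contaminated, 2)
  expect_error(substance_prevalence(st, "drugY"),
               class = "carryprev_unknown_substance")
})

test_that("adjusted prevalence equals a brute-force recount on random datasets", {
  for (seed in c(2, 3, 4)) {
    st <- random_statuses(40, c("a", "b", "c"), seed)
    est <- substance_prevalence(st)
    for (s in c("a", "b", "c")) {
      rows <- st[st$substance == s, ]
      n_pos <- 0; n_con <- 0
      for (i in seq_len(nrow(rows))) {
        if (rows$status[i] == "positive") n_pos <- n_pos + 1
        if (rows$status[i] == "contaminated") n_con <- n_con + 1
      }
      expect_equal(est$prevalence_pct[est$label == s],
                   100 * n_pos / (nrow(rows) - n_con))
    }
  }
})

test_that("adding a contaminated sample cannot decrease a substance's prevalence", {
  st <- random_statuses(30, "a", seed = 9)
  base <- substance_prevalence(st)
  extra <- st[1, ]
  extra$slot <- 31L
  extra$status <- "contaminated"
  more <- substance_prevalence(dplyr::bind_rows(st, extra))
  expect_equal(more$n_positive, base$n_positive)
  expect_gte(more$prevalence_pct, base$prevalence_pct)
})

test_that("whole-sample shares partition the dataset and match printed-style counts", {
  ss <- tibble::tibble(
    site_id = "hut", cassette_id = "c1", slot = 1:430,
    status = rep(c("positive", "negative", "contaminated"), c(154, 210, 66))
  )
  rates <- sample_status_rates(ss)
  expect_equal(round(rates$share_pct, 1), c(35.8, 48.8, 15.3))
  expect_equal(sum(rates$share_pct), 100)
  # all-negative dataset
  ssn <- dplyr::mutate(ss, status = "negative")
  expect_equal(sample_status_rates(ssn)$share_pct, c(0, 100, 0))
  expect_error(sample_status_rates(ss[0, ]),
               class = "carryprev_undefined_estimate")
})

test_that("class prevalence reduces to the substance estimate for singleton classes", {
  panel <- one_substance_panel()
  st <- random_statuses(50, "acetazolamide", seed = 6)
  cls <- class_prevalence(st, panel)
  sub <- substance_prevalence(st)
  expect_equal(cls$prevalence_pct, sub$prevalence_pct)
  expect_equal(cls$ci_low_pct, sub$ci_low_pct)
  expect_error(class_prevalence(st, panel, drug_classes = "hypnotics"),
               class = "carryprev_config_error")
})

test_that("a class-positive sample counts once even when another member contaminates it", {
  panel <- substance_panel(data.frame(
    name = c("acetazolamide", "hydrochlorothiazide"),
    drug_class = "diuretics",
    use_probability = 0.1, conc_log_mean = 5, conc_log_sd = 1, lod = 5
  ))
  st <- dplyr::bind_rows(
    one_sample_statuses(acetazolamide = "positive",
                        hydrochlorothiazide = "contaminated"),
    dplyr::mutate(one_sample_statuses(acetazolamide = "negative",
                                      hydrochlorothiazide = "negative"),
                  slot = 2L)
  )
  cls <- class_prevalence(st, panel)
  expect_equal(cls$n_positive, 1)
  expect_equal(cls$n_contaminated, 0)
  expect_equal(cls$n_total, 2)
  expect_equal(cls$prevalence_pct, 50)
})

test_that("class prevalence matches brute-force set logic on random panels", {
  panel <- substance_panel(data.frame(
    name = c("a", "b", "c"), drug_class = c("d1", "d1", "d2"),
    use_probability = 0.1, conc_log_mean = 5, conc_log_sd = 1, lod = 5
  ))
  for (seed in c(13, 14)) {
    st <- random_statuses(35, c("a", "b", "c"), seed)
    cls <- class_prevalence(st, panel, drug_classes = "d1")
    # enumeration oracle: per sample, inspect the member statuses directly
    n_pos <- 0; n_con <- 0; n_tot <- 0
    for (k in unique(st$slot)) {
      members <- st$status[st$slot == k & st$substance %in% c("a", "b")]
      n_tot <- n_tot + 1
      if (any(members == "positive")) {
        n_pos <- n_pos + 1
      } else if (any(members == "contaminated")) {
        n_con <- n_con + 1
      }
    }
    expect_equal(cls$n_positive, n_pos)
    expect_equal(cls$n_contaminated, n_con)
    expect_equal(cls$prevalence_pct, 100 * n_pos / (n_tot - n_con))
  }
})

test_that("combination table keys samples by their exact positive set", {
  st <- dplyr::bind_rows(
    one_sample_statuses(a = "positive", b = "positive", c = "negative"),
    dplyr::mutate(one_sample_statuses(a = "positive", b = "positive",
                                      c = "positive"), slot = 2L),
    dplyr::mutate(one_sample_statuses(a = "positive", b = "negative",
                                      c = "negative"), slot = 3L),
    dplyr::mutate(one_sample_statuses(a = "negative", b = "contaminated",
                                      c = "negative"), slot = 4L)
  )
  combos <- combination_table(st)
  expect_equal(attr(combos, "n_multi_samples"), 2)
  expect_setequal(combos$combination, c("a + b", "a + b + c"))
  expect_equal(combos$n_pooled, c(1, 1))
  # a dataset with at most one positive per sample yields an empty table
  single <- dplyr::filter(st, slot >= 3)
  empty <- combination_table(single)
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "n_multi_samples"), 0)
})

test_that("concentration summary covers positives only and matches a two-pass oracle", {
  st <- tibble::tibble(
    site_id = "hut", cassette_id = "c1", slot = 1:5, substance = "bromazepam",
    concentration_ng_ml = c(23, 40, 0, 12, 7),
    status = c("positive", "contaminated", "negative", "negative", "negative")
  )
  s1 <- concentration_summary(st)
  expect_equal(s1$n, 1)
  expect_equal(s1$mean, 23)
  expect_true(is.na(s1$sd))
  expect_equal(c(s1$min, s1$max), c(23, 23))

  st2 <- dplyr::mutate(st, status = "positive", concentration_ng_ml = 10)
  s2 <- concentration_summary(st2)
  expect_equal(s2$mean, 10)
  expect_equal(s2$sd, 0)

  withr::with_seed(8, {
    vals <- stats::rlnorm(20, 4, 1.5)
  })
  st3 <- tibble::tibble(
    site_id = "hut", cassette_id = "c1", slot = 1:20, substance = "x",
    concentration_ng_ml = vals, status = "positive"
  )
  s3 <- concentration_summary(st3)
  # two-pass oracle
  m <- sum(vals) / length(vals)
  expect_equal(s3$mean, m)
  expect_equal(s3$sd, sqrt(sum((vals - m)^2) / (length(vals) - 1)))
  expect_true(s3$min <= s3$mean && s3$mean <= s3$max)

  # zero positives: empty summary, not an error
  expect_equal(nrow(concentration_summary(dplyr::mutate(st3, status = "negative"))), 0)
})

test_that("formatted cells print one decimal and suppress the CI when n = 1", {
  st <- tibble::tibble(
    site_id = "hut", cassette_id = "c1", slot = 1:430, substance = "x",
    concentration_ng_ml = 50,
    status = rep(c("positive", "negative"), c(89, 341))
  )
  est <- format_prevalence(substance_prevalence(st))
  expect_equal(est$formatted, "20.7 (16.9–24.5)")
  one <- tibble::tibble(
    site_id = "hut", cassette_id = "c1", slot = 1:430, substance = "x",
    concentration_ng_ml = 50,
    status = rep(c("positive", "negative"), c(1, 429))
  )
  expect_equal(format_prevalence(substance_prevalence(one))$formatted, "0.2")
})
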