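tto_quarter <- function(demo_extra, ther_lines) {
  link_raw_quarter(
    DEMO = c(demo_header, demo_extra),
    DRUG = c(drug_header,
             vapply(seq_along(demo_extra), function(i) {
               pid <- strsplit(demo_extra[i], "$", fixed = TRUE)[[1]][1]
               cid <- strsplit(demo_extra[i], "$", fixed = TRUE)[[1]][2]
               drug_line(pid, cid, name = "VICTOZA")
             }, character(1))),
    REAC = c(reac_header,
             vapply(seq_along(demo_extra), function(i) {
               pid <- strsplit(demo_extra[i], "$", fixed = TRUE)[[1]][1]
               cid <- strsplit(demo_extra[i], "$", fixed = TRUE)[[1]][2]
               reac_line(pid, cid)
             }, character(1))),
    THER = c(ther_header, ther_lines))
}

test_that("time to onset is event minus earliest full therapy start", {
  rep <- tto_quarter(
    c(demo_line("11", "1", event_dt = "20230121"),
      demo_line("21", "2", event_dt = "20230121"),   # event before start
      demo_line("31", "3", event_dt = "202301"),     # partial event date
      demo_line("41", "4", event_dt = ""),           # missing event date
      demo_line("51", "5", event_dt = "20230110")),  # missing start
    c(ther_line("11", "1", start = "20230101"),
      ther_line("11", "1", seq = "1", start = "20230115"),  # later row ignored
      ther_line("21", "2", start = "20230201"),
      ther_line("31", "3", start = "20230101"),
      ther_line("41", "4", start = "20230101"),
      ther_line("51", "5", start = "")))
  ts <- compute_tto(rep, glp1_synonyms, "liraglutide")
  expect_equal(ts$values, 20L)
  expect_equal(unname(ts$n_excluded),
               c(1L, 1L, 1L, 1L))  # missing_event, missing_start, before, partial
  expect_equal(ts$n_excluded[["event_before_start"]], 1L)
  # conservation: eligible + excluded = candidate reports
  expect_equal(length(ts$values) + sum(ts$n_excluded), 5L)
})

test_that("same-day onset yields TTO = 0", {
  rep <- tto_quarter(demo_line("11", "1", event_dt = "20230101"),
                     ther_line("11", "1", start = "20230101"))
  expect_equal(compute_tto(rep, glp1_synonyms, "liraglutide")$values, 0L)
})

test_that("eligible sample size matches the generator manifest", {
  sc <- faers_scenario(seed = 37, n_cases = 2000)
  rep <- generated_reports(sc)
  man <- generate_faers(sc)$manifest
  syn <- synth_drug_synonyms()
  for (drug in c("exenatide", "liraglutide")) {
    ts <- compute_tto(rep, syn, drug)
    expect_equal(length(ts$values),
                 sum(man$drug == drug & man$tto_observed), info = drug)
    keep <- man$drug == drug & man$tto_observed
    expect_equal(sort(ts$values), sort(man$tto_true[keep]), info = drug)
  }
})

test_that("median and quartiles use linear interpolation", {
  expect_equal(unname(median_iqr(c(0, 5, 10, 38, 100))["median"]), 10)
  q <- median_iqr(c(1, 2, 3, 4))
  expect_equal(unname(q), c(2.5, 1.75, 3.25))
  expect_error(median_iqr(numeric(0)), "insufficient")
})

test_that("sample median approaches the closed-form Weibull median", {
  set.seed(5)
  x <- rweibull(1e4, 0.5, 30)
  expect_equal(unname(median_iqr(x)["median"]), 30 * log(2)^2,
               tolerance = 0.05)
})

test_that("the Weibull MLE agrees with an independent fitter", {
  skip_if_not_installed("MASS")
  set.seed(9)
  x <- rweibull(400, 0.6, 40)
  fit <- weibull_fit(x)
  ref <- suppressWarnings(MASS::fitdistr(x, "weibull"))
  expect_equal(fit$shape, unname(ref$estimate["shape"]), tolerance = 1e-3)
  expect_equal(fit$scale, unname(ref$estimate["scale"]), tolerance = 1e-3)
  # log-scale delta-method CI reproduces the observed-information SEs
  se_log_shape <- unname(ref$sd["shape"]) / fit$shape
  expect_equal(fit$shape_ci[2] / fit$shape, exp(1.96 * se_log_shape),
               tolerance = 0.01)
})

test_that("zero onsets are shifted, degenerate samples are rejected", {
  set.seed(10)
  x <- c(rep(0L, 20), as.integer(rweibull(200, 0.5, 20)))
  fit <- weibull_fit(x)
  expect_true(fit$converged && fit$shape > 0 && fit$scale > 0)
  expect_error(weibull_fit(c(1, 1, 1, 1)), "insufficient")
  expect_error(weibull_fit(rep(3, 50)), "insufficient")
})

test_that("failure classification follows the shape CI rule", {
  mk <- function(shape, lo, hi) {
    structure(list(n = 100, shape = shape, shape_ci = c(lo, hi),
                   scale = 30, scale_ci = c(20, 40), converged = TRUE),
              class = "weibull_fit")
  }
  expect_equal(classify_failure(mk(0.46, 0.39, 0.53)), "early")
  expect_equal(classify_failure(mk(1.0, 0.9, 1.1)), "random")
  expect_equal(classify_failure(mk(1.4, 1.2, 1.6)), "wear_out")
})

test_that("classification is invariant to the time unit", {
  set.seed(11)
  x <- rweibull(300, 0.5, 40) + 0.5
  f_days <- weibull_fit(x)
  f_weeks <- weibull_fit(x / 7)
  expect_equal(f_days$shape, f_weeks$shape, tolerance = 1e-4)
  expect_equal(f_days$failure_type, f_weeks$failure_type)
  expect_equal(f_days$scale / 7, f_weeks$scale, tolerance = 1e-4)
})

test_that("distribution comparison is symmetric and detects scale shifts", {
  set.seed(12)
  a <- rweibull(300, 0.5, 108)   # long-onset profile
  b <- rweibull(300, 0.5, 10)
  same <- compare_tto(a, a)
  expect_equal(same$p, 1)
  cmp <- compare_tto(a, b)
  expect_lt(cmp$p, 0.001)
  rev <- compare_tto(b, a)
  expect_equal(cmp$z, -rev$z, tolerance = 1e-10)
  # a singleton still runs
  single <- compare_tto(5, b)
  expect_true(single$p > 0 && single$p <= 1)
})

test_that("pairwise comparisons carry Bonferroni-adjusted p-values", {
  set.seed(13)
  samples <- list(a = rweibull(100, 0.5, 50), b = rweibull(100, 0.5, 10),
                  c = rweibull(100, 0.5, 12))
  pw <- pairwise_tto(samples)
  expect_equal(nrow(pw), 3L)
  expect_equal(pw$p_adjusted, pmin(pw$p * 3, 1))
})

test_that("cumulative onset curves are monotone and end at 1", {
  set.seed(14)
  cdf <- tto_cumulative(as.integer(rweibull(200, 0.5, 20)))
  expect_true(all(diff(cdf$t) > 0))
  expect_true(all(diff(cdf$F) > 0))
  expect_equal(cdf$F[nrow(cdf)], 1)
})
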