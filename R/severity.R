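#' @title Severity classification and group comparisons
#' @description Report-level serious/non-serious classification from
#'   outcome codes, the tests used to compare demographics between the
#'   two groups (uncorrected Pearson chi-squared, Fisher's exact test,
#'   Mann-Whitney U with normal approximation), and descriptive cohort
#'   summaries.
#' @name severity
NULL

#' Classify reports as serious
#'
#' A report is serious when it carries at least one of the outcome codes
#' death (DE), life-threatening (LT), hospitalization (HO), disability
#' (DS), congenital anomaly (CA), required intervention (RI), or other
#' serious (OT).  Reports with no outcome rows are non-serious.
#'
#' @param reports a `faers_reports` object.
#' @return named logical vector, one element per report (primaryid).
#' @export
classify_serious <- function(reports) {
  out <- rep(FALSE, nrow(reports$demo))
  names(out) <- reports$demo$primaryid
  oc <- reports$outcomes
  if (!is.null(oc) && nrow(oc) > 0L) {
    serious_ids <- unique(oc$primaryid[oc$outc_cod %in% SERIOUS_OUTCOME_CODES])
    out[names(out) %in% serious_ids] <- TRUE
  }
  out
}

#' Pearson chi-squared test for a 2x2 table
#'
#' Uncorrected statistic `N(ad-bc)^2 / [(a+b)(c+d)(a+c)(b+d)]` with the
#' p-value from the chi-squared distribution on 1 df.  Callers should
#' use [fisher_exact_2x2()] when any expected cell count is below 5.
#'
#' @param a,b,c,d cell counts.
#' @return list with `chi2`, `p`.
#' @export
pearson_chi2_2x2 <- function(a, b, c, d) {
  chi2 <- chi2_2x2(c(a, b, c, d))
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by summing the probabilities of all tables with the
#' observed margins whose hypergeometric probability does not exceed that
#' of the observed table (the convention of [stats::fisher.test()],
#' which this wraps), with the conditional-MLE odds ratio.
#'
#' @param a,b,c,d cell counts.
#' @return list with `odds_ratio`, `p`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  ft <- stats::fisher.test(matrix(c(a, c, b, d), 2L, 2L))
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Mann-Whitney U test with normal approximation
#'
#' Rank-sum test of two independent samples.  `U` is the number of
#' (sample1, sample2) pairs won by sample1 (ties count one half); `Z`
#' uses the tie-corrected variance and no continuity correction, so two
#' identical samples give `Z = 0` exactly (p reported as 1).
#'
#' @param x,y numeric samples (both non-empty).
#' @return list with `u`, `z`, `p` (two-sided).
#' @export
mann_whitney_z <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("insufficient data: empty sample")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- n1 * n2 / 12 * (n + 1 - tie_term)
  if (v <= 0 || u == mu) {
    return(list(u = u, z = 0, p = 1))
  }
  z <- (u - mu) / sqrt(v)
  list(u = u, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Compare demographics between serious and non-serious reports
#'
#' For one drug cohort: gender proportions by uncorrected Pearson
#' chi-squared when all expected cell counts are at least 5, otherwise
#' Fisher's exact test; age and weight by the Mann-Whitney U test.  The
#' chosen test is recorded per comparison.
#'
#' @param reports a deduplicated (typically SOC-filtered, drug-selected)
#'   `faers_reports` cohort.
#' @param drug label carried into the output.
#' @return data.frame with one row per comparison: `variable`,
#'   `test`, `statistic`, `p`, group sizes and group summaries (counts
#'   for gender; median/IQR for age and weight).
#' @export
compare_severity <- function(reports, drug = NA_character_) {
  serious <- classify_serious(reports)
  demo <- reports$demo
  rows <- list()

  known_sex <- demo$sex %in% c("female", "male")
  a <- sum(known_sex & demo$sex == "male" & serious)
  b <- sum(known_sex & demo$sex == "male" & !serious)
  c_ <- sum(known_sex & demo$sex == "female" & serious)
  d <- sum(known_sex & demo$sex == "female" & !serious)
  n <- a + b + c_ + d
  if (n > 0 && all(c(a + b, c_ + d, a + c_, b + d) > 0)) {
    expected <- outer(c(a + b, c_ + d), c(a + c_, b + d)) / n
    if (all(expected >= 5)) {
      tst <- pearson_chi2_2x2(a, b, c_, d)
      rows$gender <- data.frame(
        drug = drug, variable = "gender", test = "pearson_chi2",
        statistic = tst$chi2, p = tst$p,
        n_serious = a + c_, n_nonserious = b + d,
        summary_serious = sprintf("male %d / female %d", a, c_),
        summary_nonserious = sprintf("male %d / female %d", b, d),
        stringsAsFactors = FALSE)
    } else {
      tst <- fisher_exact_2x2(a, b, c_, d)
      rows$gender <- data.frame(
        drug = drug, variable = "gender", test = "fisher_exact",
        statistic = tst$odds_ratio, p = tst$p,
        n_serious = a + c_, n_nonserious = b + d,
        summary_serious = sprintf("male %d / female %d", a, c_),
        summary_nonserious = sprintf("male %d / female %d", b, d),
        stringsAsFactors = FALSE)
    }
  }

  for (var in c("age_years", "weight_kg")) {
    vs <- demo[[var]][serious]; vn <- demo[[var]][!serious]
    vs <- vs[!is.na(vs)]; vn <- vn[!is.na(vn)]
    label <- if (var == "age_years") "age" else "weight"
    if (length(vs) > 0L && length(vn) > 0L) {
      tst <- mann_whitney_z(vs, vn)
      fmt <- function(v) {
        q <- median_iqr(v)
        sprintf("%.5g (%.5g-%.5g)", q["median"], q["q1"], q["q3"])
      }
      rows[[label]] <- data.frame(
        drug = drug, variable = label, test = "mann_whitney",
        statistic = tst$z, p = tst$p,
        n_serious = length(vs), n_nonserious = length(vn),
        summary_serious = fmt(vs), summary_nonserious = fmt(vn),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, unname(rows))
  if (is.null(out)) {
    out <- data.frame(drug = character(), variable = character(),
                      test = character(), statistic = numeric(),
                      p = numeric(), n_serious = integer(),
                      n_nonserious = integer(),
                      summary_serious = character(),
                      summary_nonserious = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Percentage as printed in cohort tables
#'
#' The convention used throughout [summarize_cohort()]: `100 * n / total`
#' rounded half-up to two decimals (so 13,817 of 22,404 prints 61.67).
#'
#' @param n numerator count(s).
#' @param total denominator.
#' @return numeric percentage(s) with two decimals.
#' @export
cohort_percent <- function(n, total) {
  if (length(total) == 1L) total <- rep(total, length(n))
  out <- rep(NA_real_, length(n))
  ok <- total > 0
  out[ok] <- as.numeric(sprintf("%.2f", 100 * n[ok] / total[ok]))
  out
}

band_factor <- function(x, breaks, labels) {
  out <- rep("unknown", length(x))
  ok <- !is.na(x)
  out[ok] <- as.character(cut(x[ok], breaks = breaks, labels = labels,
                              right = FALSE))
  out
}

#' Descriptive summary of a report cohort
#'
#' Counts and percentages by gender, weight band (<80, 80-100, >100 kg,
#' unknown), age band (<18, 18-44, 45-65, >65 years, unknown), reporter
#' occupation, country (US / non-US / unknown) and outcome category,
#' plus medians with interquartile ranges for age and weight.
#' Demographic percentages use the total report count as denominator;
#' outcome-category percentages use the serious-report count, and the
#' serious/non-serious split uses the total of outcome-classified
#' reports.  All percentages are formed with [cohort_percent()].
#'
#' @param reports a deduplicated `faers_reports` cohort.
#' @param drug label carried into the output.
#' @return list of data.frames (`gender`, `weight`, `age`, `occupation`,
#'   `country`, `outcomes`) plus `medians` and `n`; class
#'   `cohort_summary`.
#' @export
summarize_cohort <- function(reports, drug = NA_character_) {
  demo <- reports$demo
  n <- nrow(demo)
  count_pct <- function(x, levels, total = n) {
    cnt <- vapply(levels, function(l) sum(x == l), integer(1))
    data.frame(category = levels, n = cnt,
               pct = cohort_percent(cnt, total),
               stringsAsFactors = FALSE)
  }

  gender <- count_pct(demo$sex, c("female", "male", "unknown"))

  wband <- band_factor(demo$weight_kg, c(-Inf, 80, 100, Inf),
                       c("<80", "80-100", ">100"))
  weight <- count_pct(wband, c("<80", "80-100", ">100", "unknown"))

  aband <- band_factor(demo$age_years, c(-Inf, 18, 45, 65, Inf),
                       c("<18", "18-44", "45-65", ">65"))
  # cut(right=FALSE) puts 65 into ">65"; the table convention is 45-65
  # inclusive of 65
  aband[!is.na(demo$age_years) & demo$age_years == 65] <- "45-65"
  age <- count_pct(aband, c("<18", "18-44", "45-65", ">65", "unknown"))

  occupation <- count_pct(demo$occupation,
                          c("consumer", "physician", "health-professional",
                            "pharmacist", "other", "lawyer", "unknown"))

  ctry <- ifelse(is.na(demo$country), "unknown",
                 ifelse(toupper(demo$country) %in% c("US", "USA"),
                        "US", "non-US"))
  country <- count_pct(ctry, c("US", "non-US", "unknown"))

  serious <- classify_serious(reports)
  n_serious <- sum(serious)
  n_nonserious <- n - n_serious
  outc_labels <- c(DE = "death", DS = "disability", HO = "hospitalization",
                   LT = "life-threatening", OT = "other-serious",
                   RI = "required-intervention", CA = "congenital-anomaly")
  oc <- reports$outcomes
  code_counts <- vapply(names(outc_labels), function(code) {
    if (is.null(oc)) 0L else length(unique(oc$primaryid[oc$outc_cod == code]))
  }, integer(1))
  outcomes <- rbind(
    data.frame(category = c("non-serious", "serious"),
               n = c(n_nonserious, n_serious),
               pct = cohort_percent(c(n_nonserious, n_serious),
                                    n_serious + n_nonserious),
               stringsAsFactors = FALSE),
    data.frame(category = unname(outc_labels), n = unname(code_counts),
               pct = cohort_percent(unname(code_counts), n_serious),
               stringsAsFactors = FALSE))

  med <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(c(median = NA_real_, q1 = NA_real_, q3 = NA_real_))
    median_iqr(v)
  }
  medians <- rbind(
    data.frame(variable = "age_years", t(med(demo$age_years))),
    data.frame(variable = "weight_kg", t(med(demo$weight_kg))))

  structure(list(drug = drug, n = n, gender = gender, weight = weight,
                 age = age, occupation = occupation, country = country,
                 outcomes = outcomes, medians = medians),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %s: %d reports\n", x$drug, x$n))
  for (sec in c("gender", "age", "weight", "country", "outcomes")) {
    cat(" ", sec, ":\n", sep = "")
    df <- x[[sec]]
    for (i in seq_len(nrow(df))) {
      cat(sprintf("    %-22s %6d (%s%%)\n", df$category[i], df$n[i],
                  formatC(df$pct[i], format = "f", digits = 2)))
    }
  }
  invisible(x)
}

#' Flatten a cohort summary to one data.frame
#' @param summary a `cohort_summary`.
#' @return data.frame with columns `section`, `category`, `n`, `pct`.
#' @export
cohort_summary_table <- function(summary) {
  secs <- c("gender", "weight", "age", "occupation", "country", "outcomes")
  do.call(rbind, lapply(secs, function(s) {
    cbind(section = s, summary[[s]], stringsAsFactors = FALSE)
  }))
}
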