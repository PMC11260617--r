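test_that("any serious outcome code marks the report serious", {
  rep <- link_raw_quarter(
    DEMO = c(demo_header, demo_line("11", "1"), demo_line("21", "2"),
             demo_line("31", "3")),
    DRUG = c(drug_header, drug_line("11", "1"), drug_line("21", "2"),
             drug_line("31", "3")),
    REAC = c(reac_header, reac_line("11", "1"), reac_line("21", "2"),
             reac_line("31", "3")),
    OUTC = c(outc_header, paste("11", "1", "HO", sep = "$")))
  s <- classify_serious(rep)
  expect_equal(unname(s), c(TRUE, FALSE, FALSE))
})

test_that("serious classification agrees with the generator truth", {
  sc <- faers_scenario(seed = 13, n_cases = 1500, serious_prob = 0.4)
  rep <- generated_reports(sc)
  man <- generate_faers(sc)$manifest
  s <- classify_serious(rep)
  expect_equal(unname(s[match(man$primaryid_latest, names(s))]), man$serious)
  expect_equal(mean(man$serious), 0.4, tolerance = 0.05)
})

test_that("pearson chi2 matches stats::chisq.test without correction", {
  set.seed(55)
  for (i in 1:20) {
    x <- sample(20:400, 4, replace = TRUE)
    got <- pearson_chi2_2x2(x[1], x[2], x[3], x[4])
    ref <- stats::chisq.test(matrix(c(x[1], x[3], x[2], x[4]), 2),
                             correct = FALSE)
    expect_equal(got$chi2, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
})

# Exhaustive two-sided Fisher p: sum hypergeometric probabilities not
# exceeding that of the observed table.
enum_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  sum(probs[probs <= dhyper(a, m, n, k) * (1 + 1e-7)])
}

test_that("fisher exact p equals exhaustive enumeration for small margins", {
  expect_equal(fisher_exact_2x2(1, 9, 11, 3)$p, enum_fisher_p(1, 9, 11, 3),
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(5, 5, 5, 5)$p, 1)
  # the all-or-nothing table attains the smallest p for its margins
  p_ext <- fisher_exact_2x2(0, 10, 10, 0)$p
  expect_equal(p_ext, enum_fisher_p(0, 10, 10, 0), tolerance = 1e-12)
  for (a in 0:10) {
    expect_gte(enum_fisher_p(a, 10 - a, 10 - a, a), p_ext)
  }
  set.seed(66)
  for (i in 1:20) {
    x <- sample(0:15, 4, replace = TRUE)
    if (sum(x) == 0) next
    expect_equal(fisher_exact_2x2(x[1], x[2], x[3], x[4])$p,
                 enum_fisher_p(x[1], x[2], x[3], x[4]), tolerance = 1e-12)
  }
})

test_that("identical samples give U at its null mean and Z exactly zero", {
  got <- mann_whitney_z(c(3, 3, 3), c(3, 3, 3))
  expect_equal(got$u, 4.5)
  expect_equal(got$z, 0)
  expect_equal(got$p, 1)
})

test_that("fully separated samples give U = 0 and the permutation tail 0.05", {
  got <- mann_whitney_z(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$u, 0)
  # brute force over all 20 rank assignments: one-sided tail of U <= 0
  combos <- combn(6, 3)
  vals <- 1:6
  u_all <- apply(combos, 2, function(ix) {
    sum(rank(vals)[ix]) - 3 * 4 / 2
  })
  expect_equal(mean(u_all <= got$u), 0.05)
})

test_that("U, Z and p match wilcox.test without continuity correction", {
  set.seed(77)
  for (i in 1:10) {
    x <- round(rnorm(30, 50, 10)); y <- round(rnorm(25, 55, 12))
    got <- mann_whitney_z(x, y)
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))
    expect_equal(got$u, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Z matches the standardized permutation null on large samples", {
  set.seed(88)
  x <- rweibull(200, 0.8, 30); y <- rweibull(200, 0.8, 45)
  got <- mann_whitney_z(x, y)
  pooled <- c(x, y)
  u_perm <- replicate(2000, {
    ix <- sample.int(400, 200)
    sum(rank(pooled)[ix]) - 200 * 201 / 2
  })
  z_perm <- (got$u - mean(u_perm)) / sd(u_perm)
  expect_equal(got$z, z_perm, tolerance = 0.15)
})

test_that("empty samples are rejected", {
  expect_error(mann_whitney_z(numeric(0), 1:3), "insufficient")
})

test_that("severity comparison picks the documented test per variable", {
  sc <- faers_scenario(seed = 21, n_cases = 4000)
  rep <- generated_reports(sc)
  cohort <- select_primary_suspect(rep, synth_drug_synonyms(), "exenatide")
  cmp <- compare_severity(cohort, drug = "exenatide")
  expect_setequal(cmp$variable, c("gender", "age", "weight"))
  expect_true(cmp$test[cmp$variable == "gender"] %in%
                c("pearson_chi2", "fisher_exact"))
  expect_equal(cmp$test[cmp$variable %in% c("age", "weight")],
               rep("mann_whitney", 2))
  expect_true(all(cmp$p >= 0 & cmp$p <= 1))
})

test_that("cohort percentages follow the printed-table convention", {
  expect_equal(cohort_percent(1, 3), 33.33)
  expect_equal(cohort_percent(1, 8), 12.5)
  expect_equal(cohort_percent(0, 10), 0)
  expect_true(is.na(cohort_percent(0, 0)))
})

test_that("a single male report summarizes to 100% male", {
  rep <- link_raw_quarter(
    DEMO = c(demo_header, demo_line("11", "1", sex = "M")),
    DRUG = c(drug_header, drug_line("11", "1")),
    REAC = c(reac_header, reac_line("11", "1")))
  cs <- summarize_cohort(rep, drug = "x")
  g <- cs$gender
  expect_equal(g$pct[g$category == "male"], 100)
  expect_equal(g$pct[g$category == "female"], 0)
})

test_that("banded counts conserve the cohort and percentages sum to 100", {
  sc <- faers_scenario(seed = 29, n_cases = 2500)
  rep <- generated_reports(sc)
  cs <- summarize_cohort(rep, drug = "all")
  for (sec in c("gender", "weight", "age", "occupation", "country")) {
    expect_equal(sum(cs[[sec]]$n), cs$n, info = sec)
    expect_equal(sum(cs[[sec]]$pct), 100, tolerance = 0.05, info = sec)
  }
  # age bands put the 65-year boundary in 45-65
  rep65 <- link_raw_quarter(
    DEMO = c(demo_header, demo_line("11", "1", age = "65")),
    DRUG = c(drug_header, drug_line("11", "1")),
    REAC = c(reac_header, reac_line("11", "1")))
  cs65 <- summarize_cohort(rep65)
  expect_equal(cs65$age$n[cs65$age$category == "45-65"], 1)
})
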