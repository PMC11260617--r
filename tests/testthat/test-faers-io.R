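test_that("a header plus two data lines yields two rows", {
  dir <- write_raw_quarter(
    tempfile(), DEMO = c(demo_header, demo_line("11", "1"), demo_line("21", "2")),
    DRUG = c(drug_header, drug_line("11", "1"), drug_line("21", "2")),
    REAC = c(reac_header, reac_line("11", "1"), reac_line("21", "2")))
  q <- read_faers_quarter(dir)
  expect_equal(nrow(q$tables$DEMO), 2L)
  expect_equal(nrow(q$quarantined), 0L)
})

test_that("short rows are quarantined with their line number, parsing continues", {
  dir <- write_raw_quarter(
    tempfile(),
    DEMO = c(demo_header, demo_line("11", "1"),
             "31$3$1$20230101",                      # far too few fields
             demo_line("21", "2")),
    DRUG = c(drug_header, drug_line("11", "1")),
    REAC = c(reac_header, reac_line("11", "1")))
  q <- read_faers_quarter(dir)
  expect_equal(nrow(q$tables$DEMO), 2L)
  expect_equal(q$quarantined$line, 3L)
  expect_match(q$quarantined$reason, "expected 12 fields, found 4")
})

test_that("missing mandatory tables are fatal and named", {
  dir <- write_raw_quarter(tempfile(),
                           DEMO = c(demo_header, demo_line("11", "1")),
                           DRUG = c(drug_header, drug_line("11", "1")))
  expect_error(read_faers_quarter(dir), "REAC")
  expect_error(read_faers_quarter(tempfile()), "does not exist")
})

test_that("a header that disagrees with the dialect is fatal", {
  dir <- write_raw_quarter(
    tempfile(),
    DEMO = c("primaryid$caseid$bogus", "11$1$x"),
    DRUG = c(drug_header, drug_line("11", "1")),
    REAC = c(reac_header, reac_line("11", "1")))
  expect_error(read_faers_quarter(dir), "dialect")
})

test_that("satellite rows link by primaryid and orphans are counted", {
  rep <- link_raw_quarter(
    DEMO = c(demo_header, demo_line("11", "1")),
    DRUG = c(drug_header, drug_line("11", "1", seq = "1"),
             drug_line("11", "1", seq = "2", role = "C", name = "ASPIRIN")),
    REAC = c(reac_header, reac_line("11", "1", "10012174"),
             reac_line("11", "1", "10028813"),
             reac_line("11", "1", "10047700"),
             reac_line("99", "9", "10012174")))     # no DEMO row
  expect_equal(n_reports(rep), 1L)
  expect_equal(nrow(rep$drugs), 2L)
  expect_equal(nrow(rep$reactions), 3L)
  expect_equal(unname(rep$orphan_counts[["REAC"]]), 1L)
})

test_that("age and weight are normalized to years and kilograms", {
  rep <- link_raw_quarter(
    DEMO = c(demo_header,
             demo_line("11", "1", age = "720", age_cod = "MON",
                       wt = "220", wt_cod = "LBS"),
             demo_line("21", "2", age = "6", age_cod = "DEC",
                       wt = "90000", wt_cod = "GMS"),
             demo_line("31", "3", age = "50", age_cod = "XX",
                       wt = "90", wt_cod = "??"),
             demo_line("41", "4", age = "150", age_cod = "YR",
                       wt = "900", wt_cod = "KG")),
    DRUG = c(drug_header, drug_line("11", "1")),
    REAC = c(reac_header, reac_line("11", "1")))
  expect_equal(rep$demo$age_years, c(60, 60, NA, NA))
  expect_equal(rep$demo$weight_kg, c(220 * 0.453592, 90, NA, NA))
})

test_that("deduplication keeps the latest receipt date per case", {
  rep <- link_raw_quarter(
    DEMO = c(demo_header,
             demo_line("11", "C1", fda_dt = "20220101"),
             demo_line("12", "C1", fda_dt = "20230101"),
             demo_line("21", "C2", fda_dt = "20210601")),
    DRUG = c(drug_header, drug_line("11", "C1"), drug_line("12", "C1"),
             drug_line("21", "C2")),
    REAC = c(reac_header, reac_line("11", "C1"), reac_line("12", "C1"),
             reac_line("21", "C2")))
  dd <- dedup_faers(rep)
  expect_equal(dd$demo$primaryid, c("12", "21"))
  expect_equal(attr(dd, "n_removed"), 1L)
  # satellite tables are filtered consistently
  expect_equal(sort(unique(dd$drugs$primaryid)), c("12", "21"))
})

test_that("receipt-date ties break by largest lexicographic-numeric primaryid", {
  rep <- link_raw_quarter(
    DEMO = c(demo_header,
             demo_line("15", "C1", fda_dt = "20230101"),
             demo_line("103", "C1", fda_dt = "20230101")),
    DRUG = c(drug_header, drug_line("15", "C1"), drug_line("103", "C1")),
    REAC = c(reac_header, reac_line("15", "C1"), reac_line("103", "C1")))
  dd <- dedup_faers(rep)
  expect_equal(dd$demo$primaryid, "103")
})

test_that("deduplication is idempotent and sorts output by caseid", {
  rep <- generated_reports(faers_scenario(seed = 3, n_cases = 300))
  dd2 <- dedup_faers(rep)
  expect_identical(rep$demo, dd2$demo)
  expect_false(is.unsorted(rep$demo$caseid))
})

test_that("primary-suspect selection honors role and synonym normalization", {
  rep <- link_raw_quarter(
    DEMO = c(demo_header, demo_line("11", "1"), demo_line("21", "2"),
             demo_line("31", "3")),
    DRUG = c(drug_header,
             drug_line("11", "1", role = "SS", name = "SEMAGLUTIDE"),
             drug_line("21", "2", role = "PS", name = "  ozempic "),
             drug_line("31", "3", role = "PS", name = "METFORMIN")),
    REAC = c(reac_header, reac_line("11", "1"), reac_line("21", "2"),
             reac_line("31", "3")))
  sel <- select_primary_suspect(rep, glp1_synonyms, "semaglutide")
  expect_equal(sel$demo$primaryid, "21")
  expect_error(select_primary_suspect(rep, glp1_synonyms, "notadrug"),
               "albiglutide.*exenatide")
})

test_that("a generated quarter round-trips losslessly against its manifest", {
  sc <- faers_scenario(seed = 17, n_cases = 500, duplicate_rate = 0)
  dir <- tempfile("rt_")
  synth <- generate_faers(sc, dir = dir)
  q <- read_faers_quarter(dir)
  expect_equal(unname(q$counts[["DEMO"]]), 500L)
  expect_gte(unname(q$counts[["DRUG"]]), 500L)
  rep <- link_faers_tables(q)
  expect_equal(n_reports(rep), 500L)
  # per-report reaction and drug counts equal the generator's manifest
  reac_n <- table(rep$reactions$caseid)
  man_n <- lengths(strsplit(synth$manifest$pts, ";", fixed = TRUE))
  expect_equal(unname(as.integer(reac_n[synth$manifest$caseid])), man_n)
  # demographics survive the round trip
  expect_equal(rep$demo$sex[match(synth$manifest$caseid, rep$demo$caseid)],
               synth$manifest$sex)
})

test_that("injected duplicates collapse to exactly the generated case count", {
  sc <- faers_scenario(seed = 5, n_cases = 1000, duplicate_rate = 0.1)
  dir <- tempfile("dup_")
  synth <- generate_faers(sc, dir = dir)
  n_dup <- sum(synth$manifest$n_versions > 1L)
  expect_gt(n_dup, 0L)
  rep <- link_faers_tables(read_faers_quarter(dir))
  expect_equal(n_reports(rep), 1000L + n_dup)
  dd <- dedup_faers(rep)
  expect_equal(n_reports(dd), 1000L)
  # the surviving version of each duplicated case is the later one
  expect_equal(dd$demo$primaryid, synth$manifest$primaryid_latest)
})
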