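#' @title Synthetic FAERS emulator
#' @description Generates FAERS-like quarterly ASCII files with a known
#'   ground-truth manifest: drug assignment, planted drug-event relative
#'   risks, demographics with realistic missingness, serious-outcome
#'   codes, Weibull onset times, duplicate case versions and injected
#'   date errors.  Every pipeline stage is testable against the manifest
#'   without any FAERS download.
#' @name synthetic
NULL

default_drugs <- function() {
  data.frame(
    drug = c("exenatide", "liraglutide", "dulaglutide", "semaglutide",
             "tirzepatide", "albiglutide", "background"),
    share = c(0.06, 0.05, 0.05, 0.05, 0.03, 0.01, 0.75),
    stringsAsFactors = FALSE)
}

default_terms <- function() {
  h <- load_term_hierarchy()
  pts <- h$table$pt_code
  base <- stats::setNames(rep(0.004, length(pts)), pts)
  # common background events reported with most drugs
  base[c("10028813", "10047700", "10012735", "10019211", "10013573",
         "10016256", "10000081")] <- c(0.06, 0.045, 0.04, 0.05, 0.035,
                                       0.045, 0.03)
  base[c("10061428", "10012174", "10020993", "10020635")] <-
    c(0.015, 0.01, 0.012, 0.012)
  data.frame(pt = names(base), baseline_p = unname(base),
             stringsAsFactors = FALSE)
}

default_rr <- function() {
  # planted associations: appetite suppression and dehydration for the
  # incretin-mimetic class, mirroring the known clinical profile
  glp1 <- c("exenatide", "liraglutide", "dulaglutide", "semaglutide",
            "tirzepatide", "albiglutide")
  rbind(
    expand.grid(drug = glp1, pt = "10061428", rr = 6,      # decreased appetite
                stringsAsFactors = FALSE),
    expand.grid(drug = c("liraglutide", "dulaglutide", "semaglutide",
                         "tirzepatide"),
                pt = "10012174", rr = 3, stringsAsFactors = FALSE), # dehydration
    expand.grid(drug = glp1, pt = "10016946", rr = 4,      # food craving
                stringsAsFactors = FALSE),
    expand.grid(drug = glp1, pt = "10021654", rr = 4,      # increased appetite
                stringsAsFactors = FALSE),
    expand.grid(drug = c("liraglutide", "semaglutide"),
                pt = "10012671", rr = 3, stringsAsFactors = FALSE)) # DKA
}

default_tto_params <- function() {
  # early-failure onset profiles; the exenatide-like depot formulation
  # has the longest onset scale
  data.frame(
    drug = c("exenatide", "liraglutide", "dulaglutide", "semaglutide",
             "tirzepatide", "albiglutide", "background"),
    shape = c(0.65, 0.46, 0.4, 0.58, 0.5, 0.5, 0.8),
    scale = c(110, 35.38, 20, 33, 25, 28, 60),
    stringsAsFactors = FALSE)
}

#' Scenario for the synthetic FAERS generator
#'
#' The default scenario emulates a GLP-1 receptor agonist
#' pharmacovigilance cohort: marginal demographic distributions match a
#' typical metabolism-and-nutrition adverse-event case series (61.67%
#' female, median age 61 with IQR roughly 53-68, median weight 95 kg,
#' 34.07% serious, 88.4% US reports, 79.3% consumer reporters), six
#' incretin-mimetic target drugs plus a 75% non-target background, a
#' mock PT vocabulary with planted appetite/dehydration relative risks,
#' and early-failure Weibull onset profiles.  All rates are
#' user-overridable; the seed fully determines the output.
#'
#' @param seed integer RNG seed.
#' @param n_cases number of distinct cases.
#' @param drugs data.frame `drug`, `share` (shares sum to 1; the drug id
#'   `"background"` marks non-target exposure).
#' @param terms data.frame `pt`, `baseline_p` (per-case reporting
#'   probability of each PT at relative risk 1).
#' @param rr data.frame `drug`, `pt`, `rr`: relative-risk multipliers
#'   (>= 0) applied to `baseline_p`; unlisted pairs have RR 1.
#' @param serious_prob global probability that a case is serious.
#' @param serious_rr optional data.frame `drug`, `pt`, `prob` overriding
#'   the serious probability for cases carrying that pair.
#' @param demographics list with `female`, `male` (remainder unknown),
#'   `age_median`, `age_sd`, `age_missing`, `weight_meanlog`,
#'   `weight_sdlog`, `weight_missing`, `us_share`, `country_missing`,
#'   `occupation` (named probabilities).
#' @param tto_params data.frame `drug`, `shape`, `scale`: Weibull onset
#'   parameters in days.
#' @param duplicate_rate fraction of cases emitted in two report
#'   versions.
#' @param bad_date_rate fraction of event-dated cases whose event date
#'   is corrupted (half set before the therapy start, half truncated to
#'   a partial year-month date).
#' @param event_missing_rate fraction of cases with no event date.
#' @param start_missing_rate fraction of cases with no therapy start
#'   date.
#' @return object of class `faers_scenario`.
#' @export
faers_scenario <- function(seed = 1L,
                           n_cases = 5000L,
                           drugs = default_drugs(),
                           terms = default_terms(),
                           rr = default_rr(),
                           serious_prob = 0.3407,
                           serious_rr = NULL,
                           demographics = list(
                             female = 0.6167, male = 0.3430,
                             age_median = 61, age_sd = 11.1,
                             age_missing = 0.3791,
                             weight_meanlog = log(95), weight_sdlog = 0.235,
                             weight_missing = 0.608,
                             us_share = 0.8841, country_missing = 0.0007,
                             occupation = c(CN = 0.7934, MD = 0.1039,
                                            HP = 0.0186, PH = 0.0204,
                                            OT = 0.0226, LW = 0.0005,
                                            UNK = 0.0406)),
                           tto_params = default_tto_params(),
                           duplicate_rate = 0.1,
                           bad_date_rate = 0.1,
                           event_missing_rate = 0.30,
                           start_missing_rate = 0.15) {
  sc <- list(seed = as.integer(seed), n_cases = as.integer(n_cases),
             drugs = drugs, terms = terms, rr = rr,
             serious_prob = serious_prob, serious_rr = serious_rr,
             demographics = demographics, tto_params = tto_params,
             duplicate_rate = duplicate_rate, bad_date_rate = bad_date_rate,
             event_missing_rate = event_missing_rate,
             start_missing_rate = start_missing_rate)
  class(sc) <- "faers_scenario"
  validate_scenario(sc)
  sc
}

validate_scenario <- function(sc) {
  chk <- function(cond, field) {
    if (!cond) stop(sprintf("invalid scenario field '%s'", field))
  }
  chk(sc$n_cases >= 1, "n_cases")
  chk(abs(sum(sc$drugs$share) - 1) < 1e-8 && all(sc$drugs$share >= 0), "drugs")
  chk(all(sc$terms$baseline_p >= 0 & sc$terms$baseline_p <= 1), "terms")
  chk(all(sc$rr$rr >= 0), "rr")
  chk(sc$serious_prob >= 0 && sc$serious_prob <= 1, "serious_prob")
  chk(sc$duplicate_rate >= 0 && sc$duplicate_rate < 1, "duplicate_rate")
  chk(sc$bad_date_rate >= 0 && sc$bad_date_rate <= 1, "bad_date_rate")
  chk(sc$event_missing_rate >= 0 && sc$event_missing_rate <= 1,
      "event_missing_rate")
  chk(sc$start_missing_rate >= 0 && sc$start_missing_rate <= 1,
      "start_missing_rate")
  chk(all(sc$drugs$drug %in% sc$tto_params$drug), "tto_params")
  invisible(sc)
}

# Raw drug-name spellings the generator emits for each canonical drug.
SYNTH_DRUG_NAMES <- list(
  exenatide = c("EXENATIDE", "BYETTA", "Bydureon"),
  liraglutide = c("LIRAGLUTIDE", "VICTOZA", "Saxenda"),
  dulaglutide = c("DULAGLUTIDE", "TRULICITY", "Trulicity."),
  semaglutide = c("SEMAGLUTIDE", "OZEMPIC", "wegovy", "RYBELSUS"),
  tirzepatide = c("TIRZEPATIDE", "MOUNJARO"),
  albiglutide = c("ALBIGLUTIDE", "TANZEUM"),
  background = c("METFORMIN", "INSULIN GLARGINE", "LISINOPRIL",
                 "ATORVASTATIN", "AMOXICILLIN", "IBUPROFEN",
                 "OMEPRAZOLE", "LEVOTHYROXINE"))

CONCOMITANT_NAMES <- c("ASPIRIN", "METFORMIN", "VITAMIN D", "MULTIVITAMIN",
                       "LOSARTAN", "SIMVASTATIN")

#' Generate a synthetic FAERS quarter
#'
#' Draws the full report stream described by a [faers_scenario()] and
#' (optionally) writes it as a $-delimited quarter directory readable by
#' [read_faers_quarter()].  Regeneration with the same scenario is
#' byte-identical.
#'
#' @param scenario a `faers_scenario`.
#' @param dir output directory for the quarter files (created if
#'   needed); `NULL` skips writing and returns the tables in memory.
#' @return object of class `faers_synth`: list with `tables` (the seven
#'   ASCII tables as character data.frames), `manifest` (one row per
#'   case: drug, PT list, seriousness, true and observed TTO, versions,
#'   injected errors) and `scenario`.
#' @export
generate_faers <- function(scenario, dir = NULL) {
  validate_scenario(scenario)
  sc <- scenario
  set.seed(sc$seed)
  n <- sc$n_cases
  dg <- sc$demographics

  case_num <- 10000000L + seq_len(n)
  caseid <- as.character(case_num)
  primaryid <- paste0(caseid, "1")

  drug <- sample(sc$drugs$drug, n, replace = TRUE, prob = sc$drugs$share)

  # reaction draws: per-case Bernoulli over the PT list with planted RR
  pts <- sc$terms$pt
  p_mat <- matrix(rep(sc$terms$baseline_p, each = n), nrow = n)
  if (nrow(sc$rr) > 0L) {
    for (k in seq_len(nrow(sc$rr))) {
      j <- match(sc$rr$pt[k], pts)
      if (is.na(j)) next
      i <- drug == sc$rr$drug[k]
      p_mat[i, j] <- pmin(p_mat[i, j] * sc$rr$rr[k], 0.95)
    }
  }
  hit <- matrix(stats::runif(n * length(pts)), nrow = n) < p_mat
  none <- rowSums(hit) == 0L
  if (any(none)) {          # every report carries at least one reaction
    for (i in which(none)) {
      hit[i, sample(length(pts), 1L, prob = p_mat[i, ])] <- TRUE
    }
  }

  # seriousness
  sp <- rep(sc$serious_prob, n)
  if (!is.null(sc$serious_rr) && nrow(sc$serious_rr) > 0L) {
    for (k in seq_len(nrow(sc$serious_rr))) {
      j <- match(sc$serious_rr$pt[k], pts)
      if (is.na(j)) next
      i <- drug == sc$serious_rr$drug[k] & hit[, j]
      sp[i] <- sc$serious_rr$prob[k]
    }
  }
  serious <- stats::runif(n) < sp
  outc_dist <- c(HO = 0.4837, OT = 0.4146, LT = 0.0457, DE = 0.0304,
                 DS = 0.0209, RI = 0.0063, CA = 0.0004)
  outc_cod <- rep(NA_character_, n)
  outc_cod[serious] <- sample(names(outc_dist), sum(serious), replace = TRUE,
                              prob = outc_dist)

  # demographics
  sex <- sample(c("F", "M", ""), n, replace = TRUE,
                prob = c(dg$female, dg$male, 1 - dg$female - dg$male))
  age <- round(stats::rnorm(n, dg$age_median, dg$age_sd))
  age <- pmin(pmax(age, 18), 95)
  age[stats::runif(n) < dg$age_missing] <- NA
  wt <- round(stats::rlnorm(n, dg$weight_meanlog, dg$weight_sdlog), 1)
  wt[stats::runif(n) < dg$weight_missing] <- NA
  u <- stats::runif(n)
  country <- ifelse(u < dg$country_missing, "",
                    ifelse(u < dg$country_missing + dg$us_share, "US",
                           sample(c("FR", "GB", "CA", "DE", "JP"), n,
                                  replace = TRUE)))
  occ_p <- dg$occupation / sum(dg$occupation)
  occ <- sample(names(occ_p), n, replace = TRUE, prob = occ_p)
  occ[occ == "UNK"] <- ""

  # dates: therapy start, true Weibull onset, receipt
  start_date <- as.Date("2015-01-01") + sample.int(3100, n, replace = TRUE)
  ti <- match(drug, sc$tto_params$drug)
  tto_true <- floor(stats::rweibull(n, sc$tto_params$shape[ti],
                                    sc$tto_params$scale[ti]))
  event_date <- start_date + tto_true
  receipt_date <- event_date + sample.int(180, n, replace = TRUE)

  # injected missingness and date errors
  event_missing <- stats::runif(n) < sc$event_missing_rate
  start_missing <- stats::runif(n) < sc$start_missing_rate
  u_bad <- stats::runif(n)
  bad_before <- !event_missing & u_bad < sc$bad_date_rate / 2
  bad_partial <- !event_missing & !bad_before & u_bad < sc$bad_date_rate
  event_date[bad_before] <- start_date[bad_before] -
    sample.int(30, sum(bad_before), replace = TRUE)

  fmt_date <- function(d) format(d, "%Y%m%d")
  event_dt <- fmt_date(event_date)
  event_dt[bad_partial] <- substr(event_dt[bad_partial], 1, 6)
  event_dt[event_missing] <- ""
  start_dt <- fmt_date(start_date)
  start_dt[start_missing] <- ""

  tto_observed <- !event_missing & !bad_partial & !bad_before & !start_missing

  # duplicate versions: same case, higher primaryid, later receipt
  dup <- stats::runif(n) < sc$duplicate_rate
  n_versions <- 1L + as.integer(dup)

  demo <- data.frame(
    primaryid = primaryid, caseid = caseid, caseversion = "1",
    fda_dt = fmt_date(receipt_date), event_dt = event_dt,
    sex = sex,
    age = ifelse(is.na(age), "", as.character(age)),
    age_cod = ifelse(is.na(age), "", "YR"),
    wt = ifelse(is.na(wt), "", as.character(wt)),
    wt_cod = ifelse(is.na(wt), "", "KG"),
    reporter_country = country, occp_cod = occ,
    stringsAsFactors = FALSE)

  # drug rows: one PS mention + 0-2 concomitants
  name_pick <- function(d) {
    pool <- SYNTH_DRUG_NAMES[[d]]
    pool[sample.int(length(pool), 1L)]
  }
  ps_name <- vapply(drug, name_pick, character(1), USE.NAMES = FALSE)
  n_con <- sample(0:2, n, replace = TRUE, prob = c(0.5, 0.35, 0.15))
  drug_rows <- list(data.frame(
    primaryid = primaryid, caseid = caseid, drug_seq = "1",
    role_cod = "PS", drugname = ps_name, stringsAsFactors = FALSE))
  if (any(n_con > 0L)) {
    idx <- rep(seq_len(n), n_con)
    seq_no <- sequence(n_con) + 1L
    drug_rows[[2L]] <- data.frame(
      primaryid = primaryid[idx], caseid = caseid[idx],
      drug_seq = as.character(seq_no), role_cod = "C",
      drugname = sample(CONCOMITANT_NAMES, length(idx), replace = TRUE),
      stringsAsFactors = FALSE)
  }
  drug_tab <- do.call(rbind, drug_rows)
  drug_tab <- drug_tab[order(match(drug_tab$primaryid, primaryid),
                             as.integer(drug_tab$drug_seq)), , drop = FALSE]

  reac_idx <- which(hit, arr.ind = TRUE)
  reac_idx <- reac_idx[order(reac_idx[, 1L], reac_idx[, 2L]), , drop = FALSE]
  reac_tab <- data.frame(
    primaryid = primaryid[reac_idx[, 1L]], caseid = caseid[reac_idx[, 1L]],
    pt = pts[reac_idx[, 2L]], stringsAsFactors = FALSE)

  outc_tab <- data.frame(
    primaryid = primaryid[serious], caseid = caseid[serious],
    outc_cod = outc_cod[serious], stringsAsFactors = FALSE)

  ther_tab <- data.frame(
    primaryid = primaryid, caseid = caseid, dsg_drug_seq = "1",
    start_dt = start_dt, end_dt = "", stringsAsFactors = FALSE)

  indi_pts <- sample(c("10067585", "10012601", "10029883"), n, replace = TRUE,
                     prob = c(0.5, 0.3, 0.2))   # T2DM / diabetes / obesity
  indi_tab <- data.frame(
    primaryid = primaryid, caseid = caseid, indi_drug_seq = "1",
    indi_pt = indi_pts, stringsAsFactors = FALSE)

  rpsr_tab <- data.frame(
    primaryid = primaryid, caseid = caseid,
    rpsr_cod = sample(c("FGN", "SDY", "OTH"), n, replace = TRUE),
    stringsAsFactors = FALSE)

  # append duplicate versions (identical payload, new primaryid, later
  # receipt date)
  if (any(dup)) {
    di <- which(dup)
    dup_pid <- paste0(caseid[di], "2")
    d2 <- demo[di, , drop = FALSE]
    d2$primaryid <- dup_pid
    d2$caseversion <- "2"
    d2$fda_dt <- fmt_date(receipt_date[di] +
                            sample.int(400, length(di), replace = TRUE) + 30L)
    demo <- rbind(demo, d2)
    dup_copy <- function(tab) {
      t2 <- tab[tab$primaryid %in% primaryid[di], , drop = FALSE]
      t2$primaryid <- paste0(t2$caseid, "2")
      rbind(tab, t2)
    }
    drug_tab <- dup_copy(drug_tab)
    reac_tab <- dup_copy(reac_tab)
    outc_tab <- dup_copy(outc_tab)
    ther_tab <- dup_copy(ther_tab)
    indi_tab <- dup_copy(indi_tab)
    rpsr_tab <- dup_copy(rpsr_tab)
  }

  manifest <- data.frame(
    caseid = caseid, primaryid_latest = paste0(caseid, n_versions),
    drug = drug, pts = vapply(seq_len(n), function(i)
      paste(pts[hit[i, ]], collapse = ";"), character(1)),
    serious = serious,
    sex = ifelse(sex == "F", "female", ifelse(sex == "M", "male", "unknown")),
    age_years = age, weight_kg = wt,
    tto_true = tto_true,
    tto_observed = tto_observed,
    event_missing = event_missing, start_missing = start_missing,
    event_before_start = bad_before, partial_event_date = bad_partial,
    n_versions = n_versions,
    stringsAsFactors = FALSE)

  tables <- list(DEMO = demo, DRUG = drug_tab, REAC = reac_tab,
                 OUTC = outc_tab, THER = ther_tab, INDI = indi_tab,
                 RPSR = rpsr_tab)

  if (!is.null(dir)) {
    write_faers_quarter(tables, dir)
  }
  structure(list(tables = tables, manifest = manifest, scenario = sc),
            class = "faers_synth")
}

#' Write ASCII tables as a FAERS quarter directory
#'
#' @param tables named list of character data.frames (DEMO, DRUG, ...).
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_faers_quarter <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tab in names(tables)) {
    df <- tables[[tab]]
    lines <- c(paste(names(df), collapse = "$"),
               do.call(paste, c(unname(as.list(df)), sep = "$")))
    writeLines(lines, file.path(dir, paste0(tab, ".txt")))
  }
  invisible(dir)
}

#' @export
print.faers_synth <- function(x, ...) {
  cat(sprintf("<faers_synth> %d cases (%d report versions), seed %d\n",
              nrow(x$manifest), nrow(x$tables$DEMO), x$scenario$seed))
  print(table(x$manifest$drug))
  invisible(x)
}

#' Synonym table matching the synthetic generator's drug spellings
#'
#' @return a `drug_synonyms` data.frame covering every raw spelling that
#'   [generate_faers()] can emit for the non-background drugs.
#' @export
synth_drug_synonyms <- function() {
  df <- do.call(rbind, lapply(
    setdiff(names(SYNTH_DRUG_NAMES), "background"),
    function(d) data.frame(canonical_drug = d,
                           raw_name = SYNTH_DRUG_NAMES[[d]],
                           stringsAsFactors = FALSE)))
  df$raw_key <- normalize_drug_key(df$raw_name)
  class(df) <- c("drug_synonyms", class(df))
  df
}
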