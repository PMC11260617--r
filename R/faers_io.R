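#' @title FAERS quarterly ASCII ingestion
#' @description Readers for the $-delimited quarterly tables
#'   (DEMO/DRUG/REAC/OUTC/THER/INDI, with RPSR accepted and ignored),
#'   line-level quarantine of malformed rows, relational linkage into a
#'   report set, case-level deduplication, and primary-suspect drug
#'   selection.
#' @name faers_io
NULL

FAERS_TABLES <- c("DEMO", "DRUG", "REAC", "OUTC", "THER", "INDI", "RPSR")
MANDATORY_TABLES <- c("DEMO", "DRUG", "REAC")
SERIOUS_OUTCOME_CODES <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

#' Column dialect for FAERS quarterly ASCII tables
#'
#' Header map for the modern (2012Q4+) column set.  Each element names the
#' expected columns of one table; a custom map may be supplied to
#' [read_faers_quarter()] to parse other column sets.
#'
#' @return Named list of character vectors, one per table.
#' @export
faers_dialect <- function() {
  list(
    DEMO = c("primaryid", "caseid", "caseversion", "fda_dt", "event_dt",
             "sex", "age", "age_cod", "wt", "wt_cod", "reporter_country",
             "occp_cod"),
    DRUG = c("primaryid", "caseid", "drug_seq", "role_cod", "drugname"),
    REAC = c("primaryid", "caseid", "pt"),
    OUTC = c("primaryid", "caseid", "outc_cod"),
    THER = c("primaryid", "caseid", "dsg_drug_seq", "start_dt", "end_dt"),
    INDI = c("primaryid", "caseid", "indi_drug_seq", "indi_pt"),
    RPSR = c("primaryid", "caseid", "rpsr_cod")
  )
}

# Parse one $-delimited file: header line + data lines, no quoting.
# Lines whose field count differs from the header are quarantined.
parse_faers_file <- function(path, table_id, expected_header) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) {
    stop(sprintf("FAERS table %s at '%s' is empty", table_id, path))
  }
  header <- strsplit(lines[1L], "$", fixed = TRUE)[[1L]]
  header <- tolower(trimws(header))
  if (!identical(header, tolower(expected_header))) {
    stop(sprintf(
      "header of %s does not match the declared dialect\n  found:    %s\n  expected: %s",
      table_id, paste(header, collapse = ", "),
      paste(expected_header, collapse = ", ")))
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    rows <- as.data.frame(matrix(character(), 0L, length(header)),
                          stringsAsFactors = FALSE)
    names(rows) <- header
    return(list(rows = rows, quarantined = data.frame(
      table = character(), line = integer(), reason = character(),
      stringsAsFactors = FALSE)))
  }
  fields <- strsplit(body, "$", fixed = TRUE)
  # strsplit drops a trailing empty field; pad those back
  nf <- lengths(fields)
  trail <- nf == length(header) - 1L & endsWith(body, "$")
  fields[trail] <- lapply(fields[trail], function(f) c(f, ""))
  nf[trail] <- nf[trail] + 1L

  bad <- nf != length(header)
  quarantined <- data.frame(
    table = rep(table_id, sum(bad)),
    line = which(bad) + 1L,          # 1-based file line number
    reason = sprintf("expected %d fields, found %d", length(header), nf[bad]),
    stringsAsFactors = FALSE)

  good <- fields[!bad]
  rows <- as.data.frame(
    matrix(unlist(good, use.names = FALSE), nrow = length(good),
           ncol = length(header), byrow = TRUE),
    stringsAsFactors = FALSE)
  names(rows) <- header

  empty_pid <- !nzchar(trimws(rows$primaryid))
  if (any(empty_pid)) {
    quarantined <- rbind(quarantined, data.frame(
      table = table_id, line = which(!bad)[empty_pid] + 1L,
      reason = "empty primaryid", stringsAsFactors = FALSE))
    rows <- rows[!empty_pid, , drop = FALSE]
  }
  list(rows = rows, quarantined = quarantined)
}

#' Read one FAERS-style quarter directory
#'
#' Expects one file per table named `<TABLE>.txt` (case-insensitive match
#' on the table prefix, e.g. `DEMO23Q2.txt` also resolves).  Each file is
#' a single header line followed by $-delimited data lines.  Malformed
#' lines (wrong field count, empty primaryid) are quarantined with their
#' line number, never silently dropped.
#'
#' @param dir directory containing the quarter's files.
#' @param dialect header map, see [faers_dialect()].
#' @return An object of class `faers_quarter`: list with `tables` (named
#'   list of character data.frames), `quarantined` (data.frame of table,
#'   line, reason) and `counts` (rows parsed per table).
#' @export
read_faers_quarter <- function(dir, dialect = faers_dialect()) {
  if (!dir.exists(dir)) stop(sprintf("quarter directory '%s' does not exist", dir))
  files <- list.files(dir, full.names = TRUE)
  found <- list()
  for (tab in names(dialect)) {
    hit <- files[grepl(paste0("^", tab), toupper(basename(files)))]
    if (length(hit) > 1L) {
      stop(sprintf("multiple candidate files for table %s: %s",
                   tab, paste(basename(hit), collapse = ", ")))
    }
    if (length(hit) == 1L) found[[tab]] <- hit
  }
  missing <- setdiff(MANDATORY_TABLES, names(found))
  if (length(missing) > 0L) {
    stop(sprintf("mandatory FAERS table(s) missing from '%s': %s",
                 dir, paste(missing, collapse = ", ")))
  }
  tables <- list()
  quarantined <- list()
  for (tab in names(found)) {
    parsed <- parse_faers_file(found[[tab]], tab, dialect[[tab]])
    tables[[tab]] <- parsed$rows
    quarantined[[tab]] <- parsed$quarantined
  }
  quarantined <- do.call(rbind, unname(quarantined))
  structure(
    list(tables = tables,
         quarantined = quarantined,
         counts = vapply(tables, nrow, integer(1))),
    class = "faers_quarter")
}

#' @export
print.faers_quarter <- function(x, ...) {
  cat("<faers_quarter>\n")
  for (tab in names(x$tables)) {
    cat(sprintf("  %s: %d rows\n", tab, nrow(x$tables[[tab]])))
  }
  cat(sprintf("  quarantined lines: %d\n", nrow(x$quarantined)))
  invisible(x)
}

normalize_sex <- function(x) {
  x <- toupper(trimws(x))
  out <- rep("unknown", length(x))
  out[x == "F"] <- "female"
  out[x == "M"] <- "male"
  out
}

OCCUPATION_CODES <- c(CN = "consumer", MD = "physician", PH = "pharmacist",
                      HP = "health-professional", OT = "other", LW = "lawyer")

normalize_occupation <- function(x) {
  x <- toupper(trimws(x))
  out <- unname(OCCUPATION_CODES[x])
  out[is.na(out)] <- "unknown"
  out
}

# Age to years.  Unrecognized unit codes and out-of-bounds values -> NA.
normalize_age <- function(age, age_cod, bounds = c(0, 120)) {
  v <- suppressWarnings(as.numeric(age))
  f <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52.18,
         DY = 1 / 365.25, HR = 1 / 8766)
  cod <- toupper(trimws(age_cod))
  cod[cod == ""] <- "YR"                      # blank unit: FAERS convention is years
  fac <- unname(f[cod])
  out <- v * fac
  out[is.na(fac)] <- NA_real_
  out[!is.na(out) & (out < bounds[1] | out > bounds[2])] <- NA_real_
  out
}

# Weight to kilograms.
normalize_weight <- function(wt, wt_cod, bounds = c(1, 500)) {
  v <- suppressWarnings(as.numeric(wt))
  f <- c(KG = 1, KGS = 1, LBS = 0.453592, IB = 0.453592, GMS = 1e-3)
  cod <- toupper(trimws(wt_cod))
  cod[cod == ""] <- "KG"
  fac <- unname(f[cod])
  out <- v * fac
  out[is.na(fac)] <- NA_real_
  out[!is.na(out) & (out < bounds[1] | out > bounds[2])] <- NA_real_
  out
}

#' Link parsed FAERS tables into a report set
#'
#' Attaches DRUG/REAC/OUTC/THER/INDI rows to their DEMO row by
#' `primaryid` and normalizes demographics (sex labels, age to years,
#' weight to kg, occupation codes, receipt and event dates).  Rows in
#' satellite tables whose `primaryid` has no DEMO row are dropped and
#' counted.  One or more quarters may be linked together.
#'
#' @param ... one or more `faers_quarter` objects.
#' @param age_bounds,weight_bounds plausibility bounds; values outside are
#'   set missing.
#' @return An object of class `faers_reports`: list of data.frames
#'   `demo`, `drugs`, `reactions`, `outcomes`, `therapies`, `indications`
#'   plus `orphan_counts` (satellite rows without a DEMO row).
#' @export
link_faers_tables <- function(..., age_bounds = c(0, 120),
                              weight_bounds = c(1, 500)) {
  quarters <- list(...)
  if (length(quarters) == 1L && is.list(quarters[[1L]]) &&
      !inherits(quarters[[1L]], "faers_quarter")) {
    quarters <- quarters[[1L]]
  }
  stopifnot(length(quarters) >= 1L,
            all(vapply(quarters, inherits, logical(1), "faers_quarter")))

  pool <- function(tab) {
    parts <- lapply(quarters, function(q) q$tables[[tab]])
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (length(parts) == 0L) return(NULL)
    do.call(rbind, parts)
  }

  demo_raw <- pool("DEMO")
  rd <- faers_parse_date(demo_raw$fda_dt)
  ed <- faers_parse_date(demo_raw$event_dt)
  demo <- data.frame(
    primaryid = trimws(demo_raw$primaryid),
    caseid = trimws(demo_raw$caseid),
    receipt_date = rd$date,
    sex = normalize_sex(demo_raw$sex),
    age_years = normalize_age(demo_raw$age, demo_raw$age_cod, age_bounds),
    weight_kg = normalize_weight(demo_raw$wt, demo_raw$wt_cod, weight_bounds),
    country = ifelse(nzchar(trimws(demo_raw$reporter_country)),
                     trimws(demo_raw$reporter_country), NA_character_),
    occupation = normalize_occupation(demo_raw$occp_cod),
    event_date = ed$date,
    event_precision = ed$precision,
    stringsAsFactors = FALSE)

  known <- demo$primaryid
  orphan_counts <- integer()
  attach_tab <- function(tab) {
    rows <- pool(tab)
    if (is.null(rows)) {
      orphan_counts[[tab]] <<- 0L
      return(NULL)
    }
    rows$primaryid <- trimws(rows$primaryid)
    orphan <- !(rows$primaryid %in% known)
    orphan_counts[[tab]] <<- sum(orphan)
    rows[!orphan, , drop = FALSE]
  }

  drugs <- attach_tab("DRUG")
  if (!is.null(drugs)) {
    drugs$role_cod <- toupper(trimws(drugs$role_cod))
  }
  reactions <- attach_tab("REAC")
  outcomes <- attach_tab("OUTC")
  if (!is.null(outcomes)) {
    outcomes$outc_cod <- toupper(trimws(outcomes$outc_cod))
  }
  therapies <- attach_tab("THER")
  if (!is.null(therapies)) {
    sd <- faers_parse_date(therapies$start_dt)
    therapies$start_date <- sd$date
    therapies$start_precision <- sd$precision
  }
  indications <- attach_tab("INDI")

  structure(
    list(demo = demo, drugs = drugs, reactions = reactions,
         outcomes = outcomes, therapies = therapies,
         indications = indications, orphan_counts = orphan_counts),
    class = "faers_reports")
}

#' @export
print.faers_reports <- function(x, ...) {
  cat(sprintf("<faers_reports> %d reports (%d cases)\n",
              nrow(x$demo), length(unique(x$demo$caseid))))
  cat(sprintf("  drug rows: %d, reaction rows: %d\n",
              if (is.null(x$drugs)) 0L else nrow(x$drugs),
              if (is.null(x$reactions)) 0L else nrow(x$reactions)))
  invisible(x)
}

# Restrict every component table of a report set to a set of primaryids.
subset_reports <- function(reports, primaryids) {
  keep <- function(df) {
    if (is.null(df)) return(NULL)
    df[df$primaryid %in% primaryids, , drop = FALSE]
  }
  reports$demo <- keep(reports$demo)
  reports$drugs <- keep(reports$drugs)
  reports$reactions <- keep(reports$reactions)
  reports$outcomes <- keep(reports$outcomes)
  reports$therapies <- keep(reports$therapies)
  reports$indications <- keep(reports$indications)
  reports
}

#' Number of reports in a report set
#' @param reports a `faers_reports` object.
#' @return integer count of DEMO rows.
#' @export
n_reports <- function(reports) nrow(reports$demo)

# "lexicographic-numeric" primaryid order: longer digit strings sort after
# shorter ones, ties broken lexicographically ("15" < "103" < "113").
primaryid_rank <- function(pid) {
  order(order(nchar(pid), pid))
}

#' Deduplicate a report set to one report per case
#'
#' FAERS distributes successive versions of the same case under one
#' `caseid` with distinct `primaryid`s.  For each case the version with
#' the latest receipt date is kept; ties are broken by the largest
#' `primaryid` under lexicographic-numeric comparison (longer digit
#' strings are larger).  Output is sorted by `caseid` for determinism.
#'
#' @param reports a `faers_reports` object.
#' @return A deduplicated `faers_reports` (one DEMO row per caseid) with
#'   attribute `n_removed` giving the number of dropped versions.
#' @export
dedup_faers <- function(reports) {
  demo <- reports$demo
  if (nrow(demo) == 0L) {
    attr(reports, "n_removed") <- 0L
    return(reports)
  }
  rd <- demo$receipt_date
  rd_key <- ifelse(is.na(rd), -Inf, as.numeric(rd))
  pid_rank <- primaryid_rank(demo$primaryid)
  ord <- order(demo$caseid, -rd_key, -pid_rank)
  demo_sorted <- demo[ord, , drop = FALSE]
  keep_rows <- !duplicated(demo_sorted$caseid)
  survivors <- demo_sorted$primaryid[keep_rows]

  out <- subset_reports(reports, survivors)
  out$demo <- out$demo[order(out$demo$caseid), , drop = FALSE]
  rownames(out$demo) <- NULL
  attr(out, "n_removed") <- nrow(demo) - length(survivors)
  out
}

#' Load a drug synonym table
#'
#' @param path delimited text file (tab- or comma-separated) with columns
#'   `canonical_drug` and `raw_name`.
#' @return data.frame with normalized (lower-case, punctuation-stripped)
#'   raw names; class `drug_synonyms`.
#' @export
load_drug_synonyms <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  stopifnot(all(c("canonical_drug", "raw_name") %in% names(df)))
  df$raw_key <- normalize_drug_key(df$raw_name)
  class(df) <- c("drug_synonyms", class(df))
  df
}

# Matching key: case-insensitive, punctuation stripped, whitespace folded.
normalize_drug_key <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[[:punct:]]", " ", x)
  gsub("[[:space:]]+", " ", trimws(x))
}

#' Map raw drug names to canonical drug ids
#'
#' Matching is case-insensitive and punctuation-stripped; names not in
#' the synonym table map to `NA` (never an error).
#'
#' @param x character vector of raw drug names.
#' @param synonyms a `drug_synonyms` table from [load_drug_synonyms()] or
#'   a data.frame with `canonical_drug` and `raw_name` columns.
#' @return character vector of canonical ids or `NA`.
#' @export
normalize_drug_names <- function(x, synonyms) {
  if (is.null(synonyms$raw_key)) synonyms$raw_key <- normalize_drug_key(synonyms$raw_name)
  idx <- match(normalize_drug_key(x), synonyms$raw_key)
  synonyms$canonical_drug[idx]
}

#' Select reports with a target drug as primary suspect
#'
#' Keeps reports having at least one DRUG row with role code `PS` whose
#' normalized name equals `target_drug`.  A `normalized_drug` column is
#' added to the drugs table of the returned set.
#'
#' @param reports a `faers_reports` object.
#' @param synonyms drug synonym table, see [load_drug_synonyms()].
#' @param target_drug canonical drug id; must appear in `synonyms`.
#' @return filtered `faers_reports`.
#' @export
select_primary_suspect <- function(reports, synonyms, target_drug) {
  configured <- unique(synonyms$canonical_drug)
  if (!(target_drug %in% configured)) {
    stop(sprintf("unknown target drug '%s'; configured drugs: %s",
                 target_drug, paste(sort(configured), collapse = ", ")))
  }
  drugs <- reports$drugs
  if (is.null(drugs) || nrow(drugs) == 0L) {
    return(subset_reports(reports, character()))
  }
  if (is.null(drugs$normalized_drug)) {
    drugs$normalized_drug <- normalize_drug_names(drugs$drugname, synonyms)
    reports$drugs <- drugs
  }
  hit <- drugs$role_cod == "PS" &
    !is.na(drugs$normalized_drug) & drugs$normalized_drug == target_drug
  subset_reports(reports, unique(drugs$primaryid[hit]))
}

#' Primary-suspect drug of every report
#'
#' @param reports a `faers_reports` object whose drugs table carries (or
#'   will be given) normalized names.
#' @param synonyms drug synonym table used to normalize names if needed.
#' @return named character vector: for each primaryid in `reports$demo`,
#'   the canonical PS drug (first PS row in table order) or `NA` when no
#'   PS row maps to a configured drug.
#' @export
ps_drug_by_report <- function(reports, synonyms) {
  drugs <- reports$drugs
  out <- rep(NA_character_, nrow(reports$demo))
  names(out) <- reports$demo$primaryid
  if (is.null(drugs) || nrow(drugs) == 0L) return(out)
  if (is.null(drugs$normalized_drug)) {
    drugs$normalized_drug <- normalize_drug_names(drugs$drugname, synonyms)
  }
  ps <- drugs[drugs$role_cod == "PS" & !is.na(drugs$normalized_drug), , drop = FALSE]
  ps <- ps[!duplicated(ps$primaryid), , drop = FALSE]
  idx <- match(names(out), ps$primaryid)
  out[!is.na(idx)] <- ps$normalized_drug[idx[!is.na(idx)]]
  out
}
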