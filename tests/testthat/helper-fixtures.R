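# Build a quarter directory from raw $-delimited line vectors.
write_raw_quarter <- function(dir, ...) {
  files <- list(...)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tab in names(files)) {
    writeLines(files[[tab]], file.path(dir, paste0(tab, ".txt")))
  }
  dir
}

demo_header <- paste(faers_dialect()$DEMO, collapse = "$")
drug_header <- paste(faers_dialect()$DRUG, collapse = "$")
reac_header <- paste(faers_dialect()$REAC, collapse = "$")
outc_header <- paste(faers_dialect()$OUTC, collapse = "$")
ther_header <- paste(faers_dialect()$THER, collapse = "$")

# One DEMO line with sensible defaults.
demo_line <- function(primaryid, caseid, fda_dt = "20230101",
                      event_dt = "", sex = "F", age = "60",
                      age_cod = "YR", wt = "90", wt_cod = "KG",
                      country = "US", occp = "CN") {
  paste(primaryid, caseid, "1", fda_dt, event_dt, sex, age, age_cod,
        wt, wt_cod, country, occp, sep = "$")
}

drug_line <- function(primaryid, caseid, seq = "1", role = "PS",
                      name = "VICTOZA") {
  paste(primaryid, caseid, seq, role, name, sep = "$")
}

reac_line <- function(primaryid, caseid, pt = "10012174") {
  paste(primaryid, caseid, pt, sep = "$")
}

ther_line <- function(primaryid, caseid, seq = "1", start = "20230101") {
  paste(primaryid, caseid, seq, start, "", sep = "$")
}

# Read + link a raw quarter in one step.
link_raw_quarter <- function(...) {
  dir <- tempfile("rawq_")
  write_raw_quarter(dir, ...)
  link_faers_tables(read_faers_quarter(dir))
}

glp1_synonyms <- load_drug_synonyms(
  system.file("extdata", "glp1_synonyms.tsv", package = "pvfaers"))

mock_hierarchy <- load_term_hierarchy()

manifest_has_pt <- function(manifest, pt) {
  vapply(strsplit(manifest$pts, ";", fixed = TRUE),
         function(v) pt %in% v, logical(1))
}

# Reports object from a generated scenario, after dedup.
generated_reports <- function(scenario) {
  dir <- tempfile("synthq_")
  generate_faers(scenario, dir = dir)
  dedup_faers(link_faers_tables(read_faers_quarter(dir)))
}
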