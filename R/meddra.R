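#' @title Term hierarchy (PT -> HLT -> SOC)
#' @description A minimal MedDRA-like three-level vocabulary: every
#'   preferred term (PT) maps to exactly one high-level term (HLT) and
#'   transitively one system organ class (SOC).  Real MedDRA is licensed,
#'   so the package ships a synthetic mock vocabulary with the same tree
#'   structure (`inst/extdata/mock_meddra.tsv`).
#' @name meddra
NULL

#' Marker returned for terms absent from the hierarchy
#' @export
UNMAPPED_TERM <- "unmapped"

#' Load a PT/HLT/SOC term hierarchy
#'
#' @param path tab-separated file with columns `pt_code`, `pt_name`,
#'   `hlt_code`, `hlt_name`, `soc_code`, `soc_name`.  Defaults to the
#'   mock vocabulary shipped with the package.
#' @param version free-text vocabulary version carried into output
#'   metadata.
#' @return Object of class `term_hierarchy` with lookup maps
#'   `pt_to_hlt`, `hlt_to_soc`, `labels`.
#' @export
load_term_hierarchy <- function(path = system.file("extdata", "mock_meddra.tsv",
                                                   package = "pvfaers"),
                                version = "mock-1.0") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  need <- c("pt_code", "pt_name", "hlt_code", "hlt_name", "soc_code", "soc_name")
  stopifnot(all(need %in% names(df)))
  if (anyDuplicated(df$pt_code)) {
    stop("term hierarchy is not a tree: duplicated pt_code entries")
  }
  hlt_soc <- unique(df[, c("hlt_code", "soc_code")])
  if (anyDuplicated(hlt_soc$hlt_code)) {
    stop("term hierarchy is not a tree: an HLT maps to multiple SOCs")
  }
  pt_to_hlt <- stats::setNames(df$hlt_code, df$pt_code)
  hlt_to_soc <- stats::setNames(hlt_soc$soc_code, hlt_soc$hlt_code)
  labels <- c(stats::setNames(df$pt_name, df$pt_code),
              stats::setNames(df$hlt_name, df$hlt_code)[!duplicated(df$hlt_code)],
              stats::setNames(df$soc_name, df$soc_code)[!duplicated(df$soc_code)])
  structure(list(pt_to_hlt = pt_to_hlt, hlt_to_soc = hlt_to_soc,
                 labels = labels, version = version, table = df),
            class = "term_hierarchy")
}

#' @export
print.term_hierarchy <- function(x, ...) {
  cat(sprintf("<term_hierarchy> %d PTs, %d HLTs, %d SOCs (version %s)\n",
              length(x$pt_to_hlt), length(x$hlt_to_soc),
              length(unique(x$hlt_to_soc)), x$version))
  invisible(x)
}

#' Roll preferred terms up the hierarchy
#'
#' @param hierarchy a `term_hierarchy`.
#' @param pt character vector of PT codes.
#' @param level `"PT"`, `"HLT"` or `"SOC"`.
#' @return character vector of term codes at the requested level; PTs not
#'   in the hierarchy yield [UNMAPPED_TERM] (never a silent drop).
#' @examples
#' h <- load_term_hierarchy()
#' meddra_rollup(h, "10012174", "SOC")  # dehydration -> metabolism SOC
#' @export
meddra_rollup <- function(hierarchy, pt, level = c("PT", "HLT", "SOC")) {
  level <- match.arg(level)
  pt <- as.character(pt)
  known <- pt %in% names(hierarchy$pt_to_hlt)
  if (level == "PT") {
    out <- pt
    out[!known] <- UNMAPPED_TERM
    return(out)
  }
  hlt <- unname(hierarchy$pt_to_hlt[pt])
  if (level == "HLT") {
    hlt[!known] <- UNMAPPED_TERM
    return(hlt)
  }
  soc <- unname(hierarchy$hlt_to_soc[hlt])
  soc[!known] <- UNMAPPED_TERM
  soc
}

#' Display label of a term code
#' @param hierarchy a `term_hierarchy`.
#' @param code character vector of PT/HLT/SOC codes.
#' @return display strings; codes without a label are returned unchanged.
#' @export
term_label <- function(hierarchy, code) {
  lab <- unname(hierarchy$labels[code])
  ifelse(is.na(lab), code, lab)
}

#' Annotate reactions with their SOC membership
#'
#' Adds an `in_soc` flag to the reactions table without dropping any
#' report, so a screen can use the whole database as reference set while
#' counting only in-SOC reactions towards terms.
#'
#' @param reports a `faers_reports` object.
#' @param hierarchy a `term_hierarchy`.
#' @param soc SOC code.
#' @return `reports` with annotated reactions.
#' @export
annotate_soc <- function(reports, hierarchy, soc) {
  reac <- reports$reactions
  if (!is.null(reac) && nrow(reac) > 0L) {
    reac$in_soc <- meddra_rollup(hierarchy, reac$pt, "SOC") == soc
    reports$reactions <- reac
  }
  reports
}

#' Restrict a report set to one system organ class
#'
#' Keeps reports with at least one reaction whose SOC rollup equals
#' `soc`.  The reactions table of the result gains an `in_soc` flag so
#' that SOC-restricted downstream counting can use only in-SOC
#' reactions.
#'
#' @param reports a `faers_reports` object.
#' @param hierarchy a `term_hierarchy`.
#' @param soc SOC code to keep.
#' @return filtered `faers_reports` with annotated reactions and
#'   attribute `soc` recording the restriction.
#' @export
filter_to_soc <- function(reports, hierarchy, soc) {
  reac <- reports$reactions
  if (is.null(reac) || nrow(reac) == 0L) {
    out <- subset_reports(reports, character())
    attr(out, "soc") <- soc
    return(out)
  }
  reac$in_soc <- meddra_rollup(hierarchy, reac$pt, "SOC") == soc
  keep <- unique(reac$primaryid[reac$in_soc])
  out <- subset_reports(reports, keep)
  out$reactions <- reac[reac$primaryid %in% keep, , drop = FALSE]
  attr(out, "soc") <- soc
  out
}
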