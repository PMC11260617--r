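#' 2x2 contingency table for a (drug, term) pair
#'
#' Counts deduplicated reports into the classic drug-by-event table:
#' `a` = target drug and target term, `b` = target drug and other terms,
#' `c` = other drugs and target term, `d` = neither.  A report counts at
#' most once per cell regardless of repeated PT mentions.  The exposed
#' group is reports whose primary-suspect (PS) drug is the target; the
#' reference ("other drugs") group is every other ingested report.
#'
#' @param reports a deduplicated `faers_reports` object.
#' @param synonyms drug synonym table used to resolve PS drugs.
#' @param target_drug canonical drug id.
#' @param term term code at `level`.
#' @param level `"PT"`, `"HLT"` or `"SOC"`.
#' @param hierarchy `term_hierarchy` used for HLT/SOC rollup.
#' @param in_soc_only if `TRUE` and the reactions table carries an
#'   `in_soc` flag (from [filter_to_soc()]), only in-SOC reactions are
#'   counted towards terms.
#' @return object of class `contingency_2x2`: list with integer fields
#'   `a`, `b`, `c`, `d`, `n` and expected count `e = (a+b)(a+c)/n`.
#' @export
build_contingency <- function(reports, synonyms, target_drug, term,
                              level = c("PT", "HLT", "SOC"),
                              hierarchy = NULL, in_soc_only = FALSE) {
  level <- match.arg(level)
  n <- n_reports(reports)
  if (n == 0L) stop("empty reference set: no reports to tabulate")
  ps <- ps_drug_by_report(reports, synonyms)
  exposed <- !is.na(ps) & ps == target_drug

  reac <- reports$reactions
  if (in_soc_only && !is.null(reac$in_soc)) {
    reac <- reac[reac$in_soc, , drop = FALSE]
  }
  codes <- if (level == "PT") reac$pt else meddra_rollup(hierarchy, reac$pt, level)
  with_term <- reports$demo$primaryid %in% unique(reac$primaryid[codes == term])

  a <- sum(exposed & with_term)
  b <- sum(exposed & !with_term)
  c_ <- sum(!exposed & with_term)
  d <- sum(!exposed & !with_term)
  contingency_2x2(a, b, c_, d, drug = target_drug, term = term, level = level)
}

#' Construct a 2x2 contingency table from counts
#'
#' @param a,b,c,d non-negative integer cell counts (`a` = drug & term).
#' @param drug,term,level optional identifiers carried in the object.
#' @return object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d, drug = NA_character_,
                            term = NA_character_, level = NA_character_) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be non-negative integers")
  }
  n <- a + b + c + d
  if (n == 0) stop("empty reference set: N = 0")
  structure(list(a = a, b = b, c = c, d = d, n = n,
                 e = (a + b) * (a + c) / n,
                 drug = drug, term = term, level = level),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat(sprintf("<contingency_2x2> %s / %s (%s)\n",
              x$drug, x$term, x$level))
  cat(sprintf("  a=%d b=%d c=%d d=%d  N=%d  E=%.3f\n",
              x$a, x$b, x$c, x$d, x$n, x$e))
  invisible(x)
}
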