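#' @title Time-to-onset analysis
#' @description Time to onset (TTO) is the interval in days from the
#'   start of therapy with the primary-suspect drug (THER start date) to
#'   the onset of the adverse event (DEMO event date).  Only full
#'   (day-precision) dates enter; records with missing or partial dates
#'   or with the event before the therapy start are excluded with
#'   per-reason counts.  Onset profiles are characterized by
#'   two-parameter Weibull fits whose shape parameter classifies the
#'   hazard as early / random / wear-out failure.
#' @name tto
NULL

#' Compute time-to-onset samples for a drug cohort
#'
#' For each report whose PS drug is `target_drug`, exposure start is the
#' earliest day-precision therapy start date among THER rows attached to
#' that report's PS target-drug mentions (matched by drug sequence
#' number); onset is the DEMO event date.  `TTO = onset - start` in
#' whole days; 0 means same-day onset.
#'
#' @param reports deduplicated `faers_reports`.
#' @param synonyms drug synonym table.
#' @param target_drug canonical drug id.
#' @param term_filter optional PT codes (character): only reports with at
#'   least one listed reaction are used.  `NULL` keeps the whole cohort.
#' @return object of class `tto_sample`: list with `drug`, `term`
#'   (`"all"` when unfiltered), integer `values` (days), and
#'   `n_excluded` (named counts: `missing_event`, `missing_start`,
#'   `event_before_start`, `partial_date`).
#' @export
compute_tto <- function(reports, synonyms, target_drug, term_filter = NULL) {
  if (!is.null(term_filter)) {
    reac <- reports$reactions
    keep <- unique(reac$primaryid[reac$pt %in% term_filter])
    reports <- subset_reports(reports, keep)
  }
  ps <- ps_drug_by_report(reports, synonyms)
  ids <- names(ps)[!is.na(ps) & ps == target_drug]

  demo <- reports$demo
  drugs <- reports$drugs
  if (is.null(drugs$normalized_drug)) {
    drugs$normalized_drug <- normalize_drug_names(drugs$drugname, synonyms)
  }
  ther <- reports$therapies

  excl <- c(missing_event = 0L, missing_start = 0L,
            event_before_start = 0L, partial_date = 0L)
  values <- integer()

  for (id in ids) {
    i <- match(id, demo$primaryid)
    eprec <- demo$event_precision[i]
    if (eprec %in% c("month", "year")) {
      excl["partial_date"] <- excl["partial_date"] + 1L
      next
    }
    if (eprec == "missing") {
      excl["missing_event"] <- excl["missing_event"] + 1L
      next
    }
    event <- demo$event_date[i]

    seqs <- drugs$drug_seq[drugs$primaryid == id & drugs$role_cod == "PS" &
                             !is.na(drugs$normalized_drug) &
                             drugs$normalized_drug == target_drug]
    th <- if (is.null(ther)) NULL else
      ther[ther$primaryid == id & ther$dsg_drug_seq %in% seqs, , drop = FALSE]
    if (is.null(th) || nrow(th) == 0L ||
        all(th$start_precision == "missing")) {
      excl["missing_start"] <- excl["missing_start"] + 1L
      next
    }
    full <- th[th$start_precision == "day", , drop = FALSE]
    if (nrow(full) == 0L) {
      excl["partial_date"] <- excl["partial_date"] + 1L
      next
    }
    start <- min(full$start_date)
    tto <- as.integer(event - start)
    if (tto < 0L) {
      excl["event_before_start"] <- excl["event_before_start"] + 1L
      next
    }
    values <- c(values, tto)
  }
  structure(list(drug = target_drug,
                 term = if (is.null(term_filter)) "all" else
                   paste(term_filter, collapse = ";"),
                 values = values, n_excluded = excl),
            class = "tto_sample")
}

#' @export
print.tto_sample <- function(x, ...) {
  cat(sprintf("<tto_sample> %s / %s: n=%d eligible, %d excluded\n",
              x$drug, x$term, length(x$values), sum(x$n_excluded)))
  if (length(x$values) > 0L) {
    q <- median_iqr(x$values)
    cat(sprintf("  median %g days (IQR %g-%g), range %d-%d\n",
                q["median"], q["q1"], q["q3"],
                min(x$values), max(x$values)))
  }
  invisible(x)
}

#' Median and interquartile range
#'
#' Linear-interpolation quantiles (type 7), the R default: for
#' `{1,2,3,4}` the quartiles are 1.75 and 3.25.
#'
#' @param x numeric sample, `n >= 1`.
#' @return named numeric: `median`, `q1`, `q3`.
#' @export
median_iqr <- function(x) {
  x <- if (inherits(x, "tto_sample")) x$values else x
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("insufficient data: empty sample")
  q <- stats::quantile(x, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Two-parameter Weibull fit of a time-to-onset sample
#'
#' Maximum-likelihood fit of shape `beta` and scale `alpha` (days).
#' Zero-day onsets are shifted to `zero_shift` (default 0.5 day) so the
#' density is defined.  95% confidence intervals come from the
#' observed-information normal approximation on the log-parameters.  A
#' location (threshold) parameter can be supplied via `location` for the
#' three-parameter variant: it is subtracted from the sample before
#' fitting (default 0, fitting what onset tables report).
#'
#' @param x numeric sample of onset days (a `tto_sample` also accepted);
#'   needs `n >= 10` non-identical values.
#' @param zero_shift replacement for zero (and sub-zero after location
#'   shift) values, in days.
#' @param location fixed threshold subtracted from the sample.
#' @param conf confidence level.
#' @return object of class `weibull_fit`: `n`, `shape`, `shape_ci`,
#'   `scale`, `scale_ci`, `loglik`, `converged`, `failure_type`.
#' @export
weibull_fit <- function(x, zero_shift = 0.5, location = 0, conf = 0.95) {
  x <- if (inherits(x, "tto_sample")) x$values else x
  x <- x[!is.na(x)] - location
  x[x <= 0] <- zero_shift
  if (length(x) < 10L || length(unique(x)) < 2L) {
    stop("insufficient data: need >= 10 non-identical onset values")
  }
  lx <- log(x)
  negll <- function(p) {
    # closed form; guard against non-finite excursions of the line search
    k <- exp(p[1]); ls <- p[2]
    v <- -sum(log(k) - ls + (k - 1) * (lx - ls) - exp(k * (lx - ls)))
    if (!is.finite(v)) 1e10 else v
  }
  p0 <- c(0, log(mean(x)))
  opt <- stats::optim(p0, negll, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  se <- sqrt(diag(solve(opt$hessian)))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  shape <- exp(opt$par[1]); scale <- exp(opt$par[2])
  shape_ci <- exp(opt$par[1] + c(-1, 1) * z * se[1])
  scale_ci <- exp(opt$par[2] + c(-1, 1) * z * se[2])
  fit <- structure(list(n = length(x), shape = shape, shape_ci = shape_ci,
                        scale = scale, scale_ci = scale_ci,
                        loglik = -opt$value,
                        converged = opt$convergence == 0L,
                        location = location),
                   class = "weibull_fit")
  fit$failure_type <- classify_failure(fit)
  fit
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf(
    "<weibull_fit> n=%d shape %.3f (%.3f-%.3f), scale %.2f (%.2f-%.2f) days\n",
    x$n, x$shape, x$shape_ci[1], x$shape_ci[2],
    x$scale, x$scale_ci[1], x$scale_ci[2]))
  cat(sprintf("  failure type: %s\n", x$failure_type))
  invisible(x)
}

#' Failure-type classification from the Weibull shape parameter
#'
#' `early` when the shape 95% CI lies entirely below 1 (decreasing
#' hazard: the risk is concentrated shortly after exposure start),
#' `wear_out` when entirely above 1 (increasing hazard), otherwise
#' `random` (CI spans 1, approximately constant hazard).  Shape is
#' dimensionless, so the label is invariant to the time unit.
#'
#' @param fit a converged `weibull_fit`.
#' @return `"early"`, `"random"` or `"wear_out"`.
#' @export
classify_failure <- function(fit) {
  stopifnot(inherits(fit, "weibull_fit"))
  if (!isTRUE(fit$converged)) stop("cannot classify an unconverged fit")
  if (fit$shape_ci[2] < 1) "early"
  else if (fit$shape_ci[1] > 1) "wear_out"
  else "random"
}

#' Compare two time-to-onset distributions
#'
#' Two-sample Mann-Whitney test on the onset values (see
#' [mann_whitney_z()]); the statistic is symmetric in its arguments up to
#' sign.
#'
#' @param sample_a,sample_b `tto_sample` objects or numeric vectors.
#' @return list with `z`, `p`.
#' @export
compare_tto <- function(sample_a, sample_b) {
  va <- if (inherits(sample_a, "tto_sample")) sample_a$values else sample_a
  vb <- if (inherits(sample_b, "tto_sample")) sample_b$values else sample_b
  tst <- mann_whitney_z(va, vb)
  list(z = tst$z, p = tst$p)
}

#' Pairwise time-to-onset comparisons with Bonferroni adjustment
#'
#' @param samples named list of `tto_sample` objects (or numeric
#'   vectors).
#' @return data.frame with one row per unordered pair: `a`, `b`, `z`,
#'   `p`, `p_adjusted` (Bonferroni across all pairs).
#' @export
pairwise_tto <- function(samples) {
  nm <- names(samples)
  stopifnot(!is.null(nm), length(samples) >= 2L)
  idx <- utils::combn(length(samples), 2L)
  rows <- apply(idx, 2L, function(ij) {
    cmp <- compare_tto(samples[[ij[1]]], samples[[ij[2]]])
    data.frame(a = nm[ij[1]], b = nm[ij[2]], z = cmp$z, p = cmp$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p, method = "bonferroni")
  out
}

#' Empirical cumulative onset curve
#'
#' Step data for cumulative time-to-onset plots: for each distinct onset
#' day `t`, the fraction of events with `TTO <= t`.
#'
#' @param sample a `tto_sample` or numeric vector.
#' @return data.frame with columns `t` (days) and `F` (cumulative
#'   fraction).
#' @export
tto_cumulative <- function(sample) {
  v <- if (inherits(sample, "tto_sample")) sample$values else sample
  v <- sort(v[!is.na(v)])
  if (length(v) == 0L) return(data.frame(t = numeric(), F = numeric()))
  t <- unique(v)
  data.frame(t = t, F = stats::ecdf(v)(t))
}
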