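#' @title Disproportionality statistics
#' @description The four signal-detection statistics computed per
#'   (drug, term) 2x2 table: reporting odds ratio (ROR) and proportional
#'   reporting ratio (PRR) with Wald confidence intervals on the log
#'   scale, the uncorrected Pearson chi-squared statistic, the Bayesian
#'   confidence propagation neural network (BCPNN) information component
#'   (IC), and the DuMouchel gamma-Poisson shrinker (EBGM/EB05).
#' @name disprop
NULL

as_cells <- function(t) {
  if (inherits(t, "contingency_2x2")) c(t$a, t$b, t$c, t$d)
  else if (is.numeric(t) && length(t) == 4L) as.numeric(t)
  else stop("expected a contingency_2x2 or a numeric vector (a, b, c, d)")
}

#' Reporting odds ratio with 95% confidence interval
#'
#' `ROR = ad / (bc)`, with a Wald interval on the natural-log scale using
#' `SE = sqrt(1/a + 1/b + 1/c + 1/d)`.  With any zero cell the estimate
#' is not defined; when `zero_correction = TRUE` the Haldane-Anscombe
#' +0.5 is added to every cell, otherwise the result is flagged not
#' estimable (all values `NA`).
#'
#' @param t a `contingency_2x2` or numeric `c(a, b, c, d)`.
#' @param conf confidence level (default 0.95).
#' @param zero_correction add 0.5 to all cells when any cell is zero.
#' @return list with `ror`, `low`, `high`, `estimable`.
#' @export
ror_ci <- function(t, conf = 0.95, zero_correction = FALSE) {
  x <- as_cells(t)
  if (any(x == 0)) {
    if (!zero_correction) {
      return(list(ror = NA_real_, low = NA_real_, high = NA_real_,
                  estimable = FALSE))
    }
    x <- x + 0.5
  }
  a <- x[1]; b <- x[2]; c_ <- x[3]; d <- x[4]
  ror <- (a * d) / (b * c_)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(ror = ror, low = exp(log(ror) - z * se), high = exp(log(ror) + z * se),
       estimable = TRUE)
}

#' Uncorrected Pearson chi-squared statistic of a 2x2 table
#'
#' `chi2 = N (ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)]`, no continuity
#' correction, 1 degree of freedom.  Identical to the classic
#' sum((O-E)^2/E) form.
#'
#' @param t a `contingency_2x2` or numeric `c(a, b, c, d)`.
#' @return the statistic (scalar); `NaN`-free: a zero margin raises an
#'   error ("degenerate table").
#' @export
chi2_2x2 <- function(t) {
  x <- as_cells(t)
  a <- x[1]; b <- x[2]; c_ <- x[3]; d <- x[4]
  n <- a + b + c_ + d
  m <- c(a + b, c_ + d, a + c_, b + d)
  if (any(m == 0)) stop("degenerate table: zero margin")
  n * (a * d - b * c_)^2 / prod(m)
}

#' Proportional reporting ratio with 95% CI and chi-squared
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]` with a Wald interval on the log scale
#' using `SE = sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`, plus the uncorrected
#' Pearson chi-squared of the same table.  Zero-cell handling as in
#' [ror_ci()].
#'
#' @inheritParams ror_ci
#' @return list with `prr`, `low`, `high`, `chi2`, `estimable`.
#' @export
prr_chi2 <- function(t, conf = 0.95, zero_correction = FALSE) {
  x <- as_cells(t)
  chi2 <- chi2_2x2(x)
  if (any(x == 0)) {
    if (!zero_correction) {
      return(list(prr = NA_real_, low = NA_real_, high = NA_real_,
                  chi2 = chi2, estimable = FALSE))
    }
    x <- x + 0.5
  }
  a <- x[1]; b <- x[2]; c_ <- x[3]; d <- x[4]
  prr <- (a / (a + b)) / (c_ / (c_ + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c_ - 1 / (c_ + d))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(prr = prr, low = exp(log(prr) - z * se), high = exp(log(prr) + z * se),
       chi2 = chi2, estimable = TRUE)
}

#' BCPNN information component with lower credibility bound
#'
#' The information component `IC = log2 P(drug, term) / (P(drug) P(term))`
#' under the Bate et al. (1998) conjugate model: independent Beta
#' posteriors for the joint and the two marginal reporting probabilities
#' with priors `alpha1 = beta1 = 1`, `alpha = beta = 2`, `gamma11 = 1`,
#' and `gamma` calibrated so that `E(IC) = 0` at independence.  Posterior
#' mean and variance of IC are computed exactly via digamma/trigamma
#' moments of the log-Beta distributions; `ic025` is the normal
#' approximation `E(IC) - multiplier * sd(IC)` (multiplier 1.96 for a
#' two-sided 95% interval; some implementations use 2).
#'
#' The priors regularize zero cells, so the function is defined for any
#' table with `N > 0`.
#'
#' @param t a `contingency_2x2` or numeric `c(a, b, c, d)`.
#' @param multiplier sd multiplier for the lower bound (default 1.96).
#' @return list with `ic`, `ic025`, `sd`.
#' @export
bcpnn_ic <- function(t, multiplier = 1.96) {
  x <- as_cells(t)
  a <- x[1]; n1 <- x[1] + x[2]; n2 <- x[1] + x[3]; n <- sum(x)
  a1 <- 1; b1 <- 1; al <- 2; be <- 2; g11 <- 1
  g <- g11 * (n + al) * (n + be) / ((n1 + a1) * (n2 + b1))
  e_l11 <- digamma(g11 + a) - digamma(g + n)
  v_l11 <- trigamma(g11 + a) - trigamma(g + n)
  e_lx <- digamma(a1 + n1) - digamma(al + n)
  v_lx <- trigamma(a1 + n1) - trigamma(al + n)
  e_ly <- digamma(b1 + n2) - digamma(be + n)
  v_ly <- trigamma(b1 + n2) - trigamma(be + n)
  ic <- (e_l11 - e_lx - e_ly) / log(2)
  sdic <- sqrt(v_l11 + v_lx + v_ly) / log(2)
  list(ic = ic, ic025 = ic - multiplier * sdic, sd = sdic)
}

# Log marginal (negative-binomial) likelihood of count a given expected E
# under a Gamma(shape, rate) prior on the relative reporting rate.
lognb <- function(a, e, shape, rate) {
  stats::dnbinom(a, size = shape, prob = rate / (rate + e), log = TRUE)
}

#' Fit the two-component gamma mixture prior of the gamma-Poisson shrinker
#'
#' DuMouchel's empirical-Bayes model: counts `a ~ Poisson(lambda * E)`
#' with `lambda` drawn from
#' `P * Gamma(alpha1, beta1) + (1-P) * Gamma(alpha2, beta2)`
#' (shape/rate).  The five hyperparameters are fitted by maximizing the
#' summed log marginal likelihood (a mixture of negative binomials) over
#' all supplied (a, E) cells, via bounded quasi-Newton (`L-BFGS-B`) on
#' log-transformed hyperparameters from the fixed documented start
#' `(0.2, 0.1, 2, 4, 1/3)`, converged to well below 1e-6 on the
#' log-likelihood.  The fit is deterministic given the cells.
#'
#' @param a integer vector of observed counts, one per (drug, term) cell.
#' @param e numeric vector of expected counts under independence.
#' @param start numeric(5): `alpha1, beta1, alpha2, beta2, mix_p`.
#' @return object of class `gps_prior`: list with the five parameters,
#'   `loglik`, `converged`, and `n_cells`.
#' @export
fit_gps_prior <- function(a, e, start = c(0.2, 0.1, 2, 4, 1 / 3)) {
  stopifnot(length(a) == length(e), all(e > 0), all(a >= 0))
  if (length(a) < 50L) {
    warning(sprintf(
      "fitting the gamma mixture prior on only %d cells; estimates may be unstable",
      length(a)))
  }
  negll <- function(p) {
    th <- c(exp(p[1:4]), stats::plogis(p[5]))
    l1 <- lognb(a, e, th[1], th[2]) + log(th[5])
    l2 <- lognb(a, e, th[3], th[4]) + log1p(-th[5])
    m <- pmax(l1, l2)
    -sum(m + log(exp(l1 - m) + exp(l2 - m)))
  }
  p0 <- c(log(start[1:4]), stats::qlogis(start[5]))
  opt <- stats::optim(p0, negll, method = "L-BFGS-B",
                      lower = c(rep(log(1e-6), 4), -20),
                      upper = c(rep(log(1e6), 4), 20),
                      control = list(factr = 1e2, maxit = 500))
  if (opt$convergence != 0L) {
    # When the likelihood is maximized by a near-degenerate component
    # (e.g. severely under-dispersed cells) L-BFGS-B stalls in its line
    # search at the box boundary; polish with a derivative-free pass on
    # the box-clamped objective, which plateaus at the boundary optimum.
    lo <- c(rep(log(1e-6), 4), -20); hi <- c(rep(log(1e6), 4), 20)
    clamped <- function(p) negll(pmin(pmax(p, lo), hi))
    polish <- stats::optim(opt$par, clamped, method = "Nelder-Mead",
                           control = list(maxit = 5000, reltol = 1e-10))
    polish$par <- pmin(pmax(polish$par, lo), hi)
    if (polish$value <= opt$value) opt <- polish
  }
  th <- c(exp(opt$par[1:4]), stats::plogis(opt$par[5]))
  structure(list(alpha1 = th[1], beta1 = th[2], alpha2 = th[3],
                 beta2 = th[4], mix_p = th[5], loglik = -opt$value,
                 converged = opt$convergence == 0L, n_cells = length(a)),
            class = "gps_prior")
}

#' @export
print.gps_prior <- function(x, ...) {
  cat(sprintf(
    "<gps_prior> P=%.3f Gamma(%.3g, %.3g) + %.3f Gamma(%.3g, %.3g)\n",
    x$mix_p, x$alpha1, x$beta1, 1 - x$mix_p, x$alpha2, x$beta2))
  cat(sprintf("  logLik %.3f over %d cells (%s)\n", x$loglik, x$n_cells,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' A fixed reference prior for the gamma-Poisson shrinker
#'
#' The documented starting point of [fit_gps_prior()] packaged as a
#' usable prior, for settings where no cell ensemble is available to fit
#' one (single-table evaluation, worked examples).
#'
#' @return a `gps_prior` object.
#' @export
gps_reference_prior <- function() {
  structure(list(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2, beta2 = 4,
                 mix_p = 1 / 3, loglik = NA_real_, converged = TRUE,
                 n_cells = 0L),
            class = "gps_prior")
}

# Posterior mixture weights and component parameters for one (a, E) cell.
gps_posterior <- function(a, e, prior) {
  lw1 <- log(prior$mix_p) + lognb(a, e, prior$alpha1, prior$beta1)
  lw2 <- log1p(-prior$mix_p) + lognb(a, e, prior$alpha2, prior$beta2)
  m <- max(lw1, lw2)
  w1 <- exp(lw1 - m) / (exp(lw1 - m) + exp(lw2 - m))
  list(w1 = w1,
       shape = c(prior$alpha1 + a, prior$alpha2 + a),
       rate = c(prior$beta1 + e, prior$beta2 + e))
}

#' Empirical Bayes geometric mean and its 5th percentile
#'
#' Posterior of the relative reporting rate `lambda` given `(a, E)` is a
#' two-component gamma mixture with components
#' `Gamma(alpha_i + a, beta_i + E)` and weights proportional to the
#' mixture's negative-binomial marginals.  `EBGM = 2^{E[log2 lambda]}`
#' (the posterior geometric mean, computed via digamma moments) and
#' `EB05` is the 5th percentile of the mixture, found by bracketed
#' root-finding on its CDF.
#'
#' @param a observed count.
#' @param e expected count; must be > 0.
#' @param prior a converged `gps_prior`.
#' @return list with `ebgm`, `eb05`.
#' @export
ebgm_eb05 <- function(a, e, prior) {
  stopifnot(inherits(prior, "gps_prior"))
  if (!isTRUE(prior$converged)) {
    stop("gamma mixture prior did not converge; refusing to shrink")
  }
  if (!is.finite(e) || e <= 0) {
    return(list(ebgm = NA_real_, eb05 = NA_real_))
  }
  po <- gps_posterior(a, e, prior)
  w <- c(po$w1, 1 - po$w1)
  elog <- sum(w * (digamma(po$shape) - log(po$rate)))
  cdf <- function(x) sum(w * stats::pgamma(x, po$shape, po$rate)) - 0.05
  qs <- stats::qgamma(0.05, po$shape, po$rate)
  lo <- min(qs) * 0.5
  hi <- max(qs) * 2 + 1e-12
  while (cdf(lo) > 0) lo <- lo / 10
  while (cdf(hi) < 0) hi <- hi * 10
  eb05 <- stats::uniroot(cdf, c(lo, hi), tol = 1e-10)$root
  list(ebgm = exp(elog), eb05 = eb05)
}

#' Joint four-method signal screen over all terms of a target drug
#'
#' Builds one 2x2 table per term observed with the target drug at the
#' requested hierarchy level (terms with `a < min_count` are skipped),
#' computes all four statistics, and applies the joint criterion: a term
#' is a signal when the ROR 95% CI lower bound exceeds 1, chi-squared is
#' at least 4 with the PRR 95% CI lower bound above 1, EB05 exceeds 2,
#' and IC025 exceeds 0 — all simultaneously.
#'
#' The gamma mixture prior is fitted once on the full (drug, term) cell
#' ensemble of the dataset (every PS drug crossed with every observed
#' term at `level`) unless a prior is supplied.
#'
#' @param reports deduplicated `faers_reports` (typically SOC-filtered).
#' @param synonyms drug synonym table.
#' @param target_drug canonical drug id.
#' @param level `"PT"` or `"HLT"` (SOC-level screening is possible but
#'   rarely meaningful with a single SOC).
#' @param hierarchy `term_hierarchy` for rollup.
#' @param min_count minimum `a` for a term to be screened (default 3).
#' @param prior optional pre-fitted `gps_prior`.
#' @param zero_correction Haldane-Anscombe correction for ROR/PRR.
#' @param ic025_multiplier sd multiplier for IC025 (default 1.96).
#' @param in_soc_only count only in-SOC reactions (see
#'   [build_contingency()]).
#' @param exclude_terms term codes excluded from screening at this level
#'   (e.g. PTs analyzed only at the HLT level).
#' @return data.frame (class `signal_screen`) with one row per screened
#'   term, sorted by term code: counts, all four statistics with interval
#'   bounds, and the logical `is_signal`.  Metadata (drug, level,
#'   min_count, prior, options) is attached as attributes.
#' @export
screen_signals <- function(reports, synonyms, target_drug,
                           level = c("PT", "HLT"), hierarchy,
                           min_count = 3L, prior = NULL,
                           zero_correction = FALSE,
                           ic025_multiplier = 1.96,
                           in_soc_only = FALSE,
                           exclude_terms = character()) {
  level <- match.arg(level)
  ps <- ps_drug_by_report(reports, synonyms)
  reac <- reports$reactions
  if (in_soc_only && !is.null(reac$in_soc)) {
    reac <- reac[reac$in_soc, , drop = FALSE]
  }
  codes <- if (level == "PT") reac$pt else meddra_rollup(hierarchy, reac$pt, level)

  # distinct (report, term) pairs
  pairs <- unique(data.frame(primaryid = reac$primaryid, term = codes,
                             stringsAsFactors = FALSE))
  pairs$ps <- ps[pairs$primaryid]
  n_total <- n_reports(reports)

  if (is.null(prior)) {
    # cell ensemble: every PS drug x observed term
    cells <- table(ps = factor(pairs$ps[!is.na(pairs$ps)]),
                   term = factor(pairs$term[!is.na(pairs$ps)]))
    drug_margin <- table(factor(ps[!is.na(ps)]))
    term_margin <- table(factor(pairs$term))
    ee <- outer(as.numeric(drug_margin[rownames(cells)]),
                as.numeric(term_margin[colnames(cells)])) / n_total
    prior <- fit_gps_prior(as.vector(cells), pmax(as.vector(ee), 1e-9))
  }

  target_terms <- pairs$term[!is.na(pairs$ps) & pairs$ps == target_drug]
  tab <- table(target_terms)
  terms <- sort(names(tab)[tab >= min_count])
  terms <- setdiff(terms, c(exclude_terms, UNMAPPED_TERM))

  rows <- lapply(terms, function(tm) {
    exposed <- !is.na(ps) & ps == target_drug
    with_term <- reports$demo$primaryid %in%
      pairs$primaryid[pairs$term == tm]
    a <- sum(exposed & with_term); b <- sum(exposed & !with_term)
    c_ <- sum(!exposed & with_term); d <- sum(!exposed & !with_term)
    ct <- contingency_2x2(a, b, c_, d, drug = target_drug, term = tm,
                          level = level)
    r <- ror_ci(ct, zero_correction = zero_correction)
    p <- prr_chi2(ct, zero_correction = zero_correction)
    ic <- bcpnn_ic(ct, multiplier = ic025_multiplier)
    eb <- ebgm_eb05(a, ct$e, prior)
    is_signal <- isTRUE(r$estimable) && isTRUE(p$estimable) &&
      r$low > 1 && p$chi2 >= 4 && p$low > 1 && eb$eb05 > 2 && ic$ic025 > 0
    data.frame(term = tm, a = a, b = b, c = c_, d = d, expected = ct$e,
               ror = r$ror, ror_low = r$low, ror_high = r$high,
               prr = p$prr, prr_low = p$low, prr_high = p$high,
               chi2 = p$chi2, ic = ic$ic, ic025 = ic$ic025,
               ebgm = eb$ebgm, ebgm05 = eb$eb05,
               is_signal = is_signal, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else data.frame()
  rownames(out) <- NULL
  structure(out, class = c("signal_screen", "data.frame"),
            drug = target_drug, level = level, min_count = min_count,
            prior = prior, zero_correction = zero_correction,
            ic025_multiplier = ic025_multiplier)
}
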