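# Disproportionality statistics on 2x2 tables:
#   ROR  = (a d)/(b c), lognormal Wald 95% CI
#   PRR  = (a/(a+b))/(c/(c+d)), lognormal Wald CI, Pearson chi-square
#   BCPNN information component IC = log2( a N / ((a+b)(a+c)) ), with the
#   classic closed-form posterior approximations EIC/VIC and IC025 = EIC - 2*sqrt(VIC).
# All functions are vectorized over the table cells.

#' BCPNN prior constants
#'
#' The standard Bate-style prior: marginal drug and event probabilities get
#' Beta(1, 1) priors (`alpha1 = beta1 = 1`, `alpha = beta = 2`) and the joint
#' cell prior parameter is `gamma11 = 1`, with `gamma` recomputed per table as
#' `gamma11 (N+alpha)(N+beta) / ((a+b+alpha1)(a+c+beta1))` so that prior
#' independence holds at the posterior margins.
#'
#' @param alpha,beta,alpha1,beta1,gamma11 positive reals.
#' @return object of class `bcpnn_priors`.
#' @export
bcpnn_priors <- function(alpha = 2, beta = 2, alpha1 = 1, beta1 = 1, gamma11 = 1) {
  v <- c(alpha = alpha, beta = beta, alpha1 = alpha1, beta1 = beta1, gamma11 = gamma11)
  if (any(!is.finite(v)) || any(v <= 0)) stop("all BCPNN priors must be positive")
  structure(as.list(v), class = "bcpnn_priors")
}

.check_cells <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  out <- data.table::data.table(a = rep_len(as.numeric(a), n),
                                b = rep_len(as.numeric(b), n),
                                c = rep_len(as.numeric(c), n),
                                d = rep_len(as.numeric(d), n))
  if (any(out < 0, na.rm = TRUE)) stop("negative contingency cell")
  out
}

#' Reporting odds ratio with lognormal Wald interval
#'
#' `ROR = ad/bc`, `se(ln ROR) = sqrt(1/a + 1/b + 1/c + 1/d)`,
#' `95% CI = exp(ln ROR +/- 1.96 se)`. A table with any zero cell is marked
#' non-evaluable (`evaluable = FALSE`, statistics `NA`) unless
#' `continuity = TRUE`, which adds 0.5 to every cell of such tables
#' (Haldane-Anscombe).
#'
#' @param a,b,c,d contingency cells (vectorized, recycled).
#' @param continuity apply the +0.5 correction to zero-cell tables.
#' @return `data.table` with columns `ror`, `ror_ci_low`, `ror_ci_high`,
#'   `se_ln_ror`, `evaluable`.
#' @export
ror_stat <- function(a, b, c, d, continuity = FALSE) {
  t <- .check_cells(a, b, c, d)
  zero <- t[, a == 0 | b == 0 | c == 0 | d == 0]
  if (continuity) {
    t[zero, `:=`(a = a + 0.5, b = b + 0.5, c = c + 0.5, d = d + 0.5)]
    zero <- rep(FALSE, nrow(t))
  }
  t[, ror := (a * d) / (b * c)]
  t[, se_ln_ror := sqrt(1 / a + 1 / b + 1 / c + 1 / d)]
  t[, `:=`(ror_ci_low = exp(log(ror) - 1.96 * se_ln_ror),
           ror_ci_high = exp(log(ror) + 1.96 * se_ln_ror))]
  t[zero, `:=`(ror = NA_real_, se_ln_ror = NA_real_,
               ror_ci_low = NA_real_, ror_ci_high = NA_real_)]
  t[, .(ror, ror_ci_low, ror_ci_high, se_ln_ror, evaluable = !zero)]
}

#' Proportional reporting ratio, Wald interval and chi-square
#'
#' `PRR = (a/(a+b)) / (c/(c+d))`,
#' `se(ln PRR) = sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`, lognormal 95% CI.
#' `chisq` is the Pearson chi-square of the 2x2 table, Yates-corrected by
#' default (the pharmacovigilance convention), computed on the uncorrected
#' cells even when `continuity = TRUE` smooths the ratio.
#'
#' @inheritParams ror_stat
#' @param yates apply the Yates continuity correction to the chi-square.
#' @return `data.table` with columns `prr`, `prr_ci_low`, `prr_ci_high`,
#'   `se_ln_prr`, `chisq`, `evaluable`.
#' @export
prr_stat <- function(a, b, c, d, yates = TRUE, continuity = FALSE) {
  t0 <- .check_cells(a, b, c, d)
  t <- data.table::copy(t0)
  zero <- t[, a == 0 | b == 0 | c == 0 | d == 0]
  if (continuity) {
    t[zero, `:=`(a = a + 0.5, b = b + 0.5, c = c + 0.5, d = d + 0.5)]
    zero <- rep(FALSE, nrow(t))
  }
  t[, prr := (a / (a + b)) / (c / (c + d))]
  t[, se_ln_prr := sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))]
  t[, `:=`(prr_ci_low = exp(log(prr) - 1.96 * se_ln_prr),
           prr_ci_high = exp(log(prr) + 1.96 * se_ln_prr))]
  out <- t[, .(prr, prr_ci_low, prr_ci_high, se_ln_prr)]
  out[zero, `:=`(prr = NA_real_, prr_ci_low = NA_real_,
                 prr_ci_high = NA_real_, se_ln_prr = NA_real_)]
  out[, chisq := chisq_2x2(t0$a, t0$b, t0$c, t0$d, yates = yates)]
  out[, evaluable := !zero]
  out[]
}

#' Pearson chi-square of a 2x2 table (vectorized)
#'
#' @inheritParams ror_stat
#' @param yates apply the Yates continuity correction
#'   (`|ad-bc| - N/2`, clamped at zero).
#' @return numeric vector of chi-square statistics (`NA` where a margin is 0).
#' @export
chisq_2x2 <- function(a, b, c, d, yates = TRUE) {
  t <- .check_cells(a, b, c, d)
  t[, N := a + b + c + d]
  num <- t[, abs(a * d - b * c)]
  if (yates) num <- pmax(num - t$N / 2, 0)
  den <- t[, (a + b) * (c + d) * (a + c) * (b + d)]
  out <- t$N * num^2 / den
  out[den == 0] <- NA_real_
  out
}

#' BCPNN information component with closed-form posterior approximation
#'
#' The observed information component is
#' `IC = log2( a N / ((a+b)(a+c)) )` (`-Inf` when `a = 0`). The posterior
#' summaries follow the classic closed forms: with
#' `gamma = gamma11 (N+alpha)(N+beta) / ((a+b+alpha1)(a+c+beta1))`,
#'
#' `EIC = log2( (a+gamma11)(N+alpha)(N+beta) / ((N+gamma)(a+b+alpha1)(a+c+beta1)) )`
#'
#' `VIC = [ (N-a+gamma-gamma11)/((a+gamma11)(1+N+gamma))
#'        + (N-(a+b)+alpha-alpha1)/((a+b+alpha1)(1+N+alpha))
#'        + (N-(a+c)+beta-beta1)/((a+c+beta1)(1+N+beta)) ] / ln(2)^2`
#'
#' and `IC025 = EIC - 2 sqrt(VIC)`. These are delta-method approximations of
#' the posterior mean and variance of IC under independent Beta posteriors
#' for the joint and marginal reporting probabilities; `method = "posterior"`
#' instead returns the exact moments of that model via digamma/trigamma
#' (`EIC = [psi(a+g11) - psi(N+g) - psi(a+b+a1) + psi(N+al) - psi(a+c+b1) +
#' psi(N+be)]/ln 2`, `VIC` the matching trigamma sum). The approximation
#' error of the closed forms is O(1/a); see the methods vignette.
#'
#' @inheritParams ror_stat
#' @param priors a [bcpnn_priors()] object.
#' @param method `"approx"` (the closed forms, default) or `"posterior"`
#'   (exact moments of the independent-Beta posterior).
#' @return `data.table` with columns `ic`, `eic`, `vic`, `ic025`.
#' @export
bcpnn_stat <- function(a, b, c, d, priors = bcpnn_priors(),
                       method = c("approx", "posterior")) {
  method <- match.arg(method)
  stopifnot(inherits(priors, "bcpnn_priors"))
  t <- .check_cells(a, b, c, d)
  al <- priors$alpha; be <- priors$beta
  a1 <- priors$alpha1; b1 <- priors$beta1; g11 <- priors$gamma11
  t[, N := a + b + c + d]
  t[, ic := log2(a * N / ((a + b) * (a + c)))]
  t[a == 0, ic := -Inf]
  t[, g := g11 * (N + al) * (N + be) / ((a + b + a1) * (a + c + b1))]
  if (method == "approx") {
    t[, eic := log2((a + g11) * (N + al) * (N + be) /
                    ((N + g) * (a + b + a1) * (a + c + b1)))]
    t[, vic := ((N - a + g - g11) / ((a + g11) * (1 + N + g)) +
                (N - (a + b) + al - a1) / ((a + b + a1) * (1 + N + al)) +
                (N - (a + c) + be - b1) / ((a + c + b1) * (1 + N + be))) / log(2)^2]
  } else {
    t[, eic := (digamma(a + g11) - digamma(N + g) -
                digamma(a + b + a1) + digamma(N + al) -
                digamma(a + c + b1) + digamma(N + be)) / log(2)]
    t[, vic := (trigamma(a + g11) - trigamma(N + g) +
                trigamma(a + b + a1) - trigamma(N + al) +
                trigamma(a + c + b1) - trigamma(N + be)) / log(2)^2]
  }
  t[, ic025 := eic - 2 * sqrt(vic)]
  t[, .(ic, eic, vic, ic025)]
}

#' Compute all three disproportionality statistics for contingency rows
#'
#' Binds ROR, PRR/chi-square and BCPNN columns onto a [tabulate_events()]
#' result and applies the signal thresholds.
#'
#' @param cont a `data.table` with at least columns `a`, `b`, `c`, `d`
#'   (e.g. from [tabulate_events()]); any other columns are carried through.
#' @param priors a [bcpnn_priors()].
#' @param yates Yates correction for the chi-square (default TRUE).
#' @param continuity +0.5 smoothing of zero-cell tables for ROR/PRR.
#' @param bcpnn_method passed to [bcpnn_stat()].
#' @return the input columns plus all statistic columns and logical flags
#'   `ror_signal`, `prr_signal`, `bcpnn_signal`, `all_three`.
#' @export
signal_table <- function(cont, priors = bcpnn_priors(), yates = TRUE,
                         continuity = FALSE, bcpnn_method = "approx") {
  dt <- data.table::as.data.table(cont)
  stopifnot(all(c("a", "b", "c", "d") %in% names(dt)))
  r <- ror_stat(dt$a, dt$b, dt$c, dt$d, continuity = continuity)
  p <- prr_stat(dt$a, dt$b, dt$c, dt$d, yates = yates, continuity = continuity)
  data.table::setnames(p, "evaluable", "prr_evaluable")
  data.table::setnames(r, "evaluable", "ror_evaluable")
  bc <- bcpnn_stat(dt$a, dt$b, dt$c, dt$d, priors = priors, method = bcpnn_method)
  out <- cbind(dt, r, p, bc)
  apply_thresholds(out)
}

#' Apply the conventional signal thresholds
#'
#' * ROR:   `a >= 3` and 95% CI lower bound `> 1`
#' * PRR:   `a >= 3`, PRR 95% CI lower bound `> 1`, and `chisq > 4`
#' * BCPNN: `IC025 > 0` (strict)
#' * `all_three`: conjunction of the three.
#'
#' A non-evaluable statistic yields a `FALSE` flag.
#'
#' @param results `data.table` with columns `a`, `ror_ci_low`, `prr_ci_low`,
#'   `chisq`, `ic025` (as produced by [signal_table()]).
#' @param a_min minimum case count (default 3).
#' @param chisq_min chi-square threshold for PRR (default 4).
#' @return the input with flag columns added (by reference semantics avoided;
#'   a copy is returned).
#' @export
apply_thresholds <- function(results, a_min = 3, chisq_min = 4) {
  dt <- data.table::copy(data.table::as.data.table(results))
  f <- function(x) !is.na(x) & x
  dt[, ror_signal := f(a >= a_min & ror_ci_low > 1)]
  dt[, prr_signal := f(a >= a_min & prr_ci_low > 1 & chisq > chisq_min)]
  dt[, bcpnn_signal := f(ic025 > 0)]
  dt[, all_three := ror_signal & prr_signal & bcpnn_signal]
  dt[]
}

#' Rank signal rows by information component
#'
#' Sorts by `ic` descending, ties broken by `a` descending then event name,
#' after removing events on the exclusion list (case-insensitive; typically
#' the merged device-use PT and indication terms) and, optionally, rows not
#' flagged by all three algorithms.
#'
#' @param results a [signal_table()] output with an `event` column.
#' @param k number of rows to keep (all if fewer qualify).
#' @param exclude character vector of event names to drop before ranking.
#' @param require_all_three keep only rows with `all_three = TRUE`.
#' @return the top-`k` rows.
#' @export
rank_by_ic <- function(results, k = 10, exclude = character(),
                       require_all_three = FALSE) {
  stopifnot(k >= 1, "event" %in% names(results))
  dt <- data.table::as.data.table(results)
  if (length(exclude)) dt <- dt[!toupper(event) %in% toupper(exclude)]
  if (require_all_three) dt <- dt[all_three == TRUE]
  data.table::setorderv(dt, c("ic", "a", "event"), order = c(-1L, -1L, 1L))
  head(dt, k)
}
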