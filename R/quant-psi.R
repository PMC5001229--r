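#' Read-class probabilities of the two-isoform model
#'
#' Under the two-isoform model, a sequenced read falls in one of three
#' classes: inclusion-specific, exclusion-specific, or shared. With
#' inclusion fraction `psi` and effective class sizes `e_inc`, `e_exc`,
#' `e_shared`, the class probabilities are
#' \deqn{p_{inc} = \psi e_{inc} / Z,\quad
#'       p_{exc} = (1-\psi) e_{exc} / Z,\quad
#'       p_{sh}  = e_{sh} / Z,}
#' with \eqn{Z = \psi (e_{inc} + e_{sh}) + (1-\psi)(e_{exc} + e_{sh})}.
#' (The shared term carries weight from both isoforms, so its numerator is
#' \eqn{\psi e_{sh} + (1-\psi) e_{sh} = e_{sh}}.)
#'
#' @param psi inclusion fraction(s) in `[0, 1]` (vectorized).
#' @param eff one-row data.frame from [effective_sizes()], or a list with
#'   `eff_inc`, `eff_exc`, `eff_shared`.
#' @return matrix with columns `p_inc`, `p_exc`, `p_shared`.
#' @export
class_probs <- function(psi, eff) {
  Z <- psi * (eff$eff_inc + eff$eff_shared) +
       (1 - psi) * (eff$eff_exc + eff$eff_shared)
  cbind(p_inc = psi * eff$eff_inc / Z,
        p_exc = (1 - psi) * eff$eff_exc / Z,
        p_shared = eff$eff_shared / Z)
}

## Log-likelihood of counts over a psi vector; 0*log(0) treated as 0 so
## that boundary psi values are handled without pseudocounts.
loglik_psi <- function(psi, n_inc, n_exc, n_shared, eff) {
  Z <- psi * (eff$eff_inc + eff$eff_shared) +
       (1 - psi) * (eff$eff_exc + eff$eff_shared)
  ll <- -(n_inc + n_exc + n_shared) * log(Z)
  if (n_inc > 0)    ll <- ll + n_inc * log(psi * eff$eff_inc)
  if (n_exc > 0)    ll <- ll + n_exc * log((1 - psi) * eff$eff_exc)
  if (n_shared > 0) ll <- ll + n_shared * log(eff$eff_shared)
  ll
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Uniform grid on [0,1] with composite-Simpson quadrature log-weights
## (trapezoid when n_grid is even).
.psi_grid <- function(n_grid) {
  h <- 1 / (n_grid - 1)
  w <- if (n_grid %% 2L == 1L && n_grid >= 3L) {
    v <- rep(c(4, 2), length.out = n_grid - 2)  # ends in 4 when n_grid is odd
    h / 3 * c(1, v, 1)
  } else {
    h * c(0.5, rep(1, n_grid - 2), 0.5)
  }
  list(psi = seq(0, 1, length.out = n_grid), logw = log(w))
}

#' Posterior distribution of PSI for one event in one condition
#'
#' Grid-based Bayesian inference for the inclusion fraction under the
#' two-isoform read-class likelihood with a uniform prior on `[0, 1]`.
#' The posterior is evaluated on `n_grid` equispaced points and normalized
#' with trapezoidal quadrature; the returned mass vector sums to 1.
#'
#' @param n_inc,n_exc,n_shared read-class counts (non-negative integers).
#' @param eff effective sizes (one-row data.frame from
#'   [effective_sizes()]).
#' @param n_grid number of grid points (default 1001).
#' @return list of class `psi_posterior`: `psi` (grid), `mass`
#'   (normalized posterior mass per point), `mean`, `ci` (central 95%
#'   credible interval), `log_marginal` (log marginal likelihood under the
#'   uniform prior), `low_information` (TRUE when all counts are zero, in
#'   which case the posterior equals the prior).
#' @export
psi_posterior <- function(n_inc, n_exc, n_shared, eff, n_grid = 1001L) {
  stopifnot(n_inc >= 0, n_exc >= 0, n_shared >= 0,
            eff$eff_inc > 0, eff$eff_exc > 0, eff$eff_shared >= 0)
  g <- .psi_grid(n_grid)
  ll <- loglik_psi(g$psi, n_inc, n_exc, n_shared, eff)
  log_marginal <- logsumexp(ll + g$logw)
  mass <- exp(ll + g$logw - log_marginal)
  ## quantiles from a trapezoid CDF of the normalized density (smoother
  ## locally than the cumulated Simpson masses)
  dens <- exp(ll - log_marginal)
  h <- g$psi[2] - g$psi[1]
  cdf <- cumsum(c(0, (dens[-1] + dens[-n_grid]) / 2 * h))
  cdf <- cdf / cdf[n_grid]
  structure(list(psi = g$psi, mass = mass,
                 mean = sum(mass * g$psi),
                 ci = c(.cdf_quantile(g$psi, cdf, 0.025),
                        .cdf_quantile(g$psi, cdf, 0.975)),
                 log_marginal = log_marginal,
                 low_information = (n_inc + n_exc + n_shared) == 0),
            class = "psi_posterior")
}

## Linear interpolation of the discrete CDF; monotone by construction.
.cdf_quantile <- function(psi, cdf, q) {
  i <- which(cdf >= q)[1]
  if (is.na(i)) return(psi[length(psi)])
  if (i == 1L) return(psi[1L] * min(1, q / cdf[1L]))
  c0 <- cdf[i - 1L]
  psi[i - 1L] + (psi[i] - psi[i - 1L]) * (q - c0) / (cdf[i] - c0)
}

#' @export
print.psi_posterior <- function(x, ...) {
  cat(sprintf("<psi_posterior> mean %.4f, 95%% CI [%.4f, %.4f]%s\n",
              x$mean, x$ci[1], x$ci[2],
              if (x$low_information) " (low information)" else ""))
  invisible(x)
}

#' Bayes factor for differential splicing between two conditions
#'
#' Compares the model with independent inclusion fractions per condition
#' (each uniform on `[0, 1]` a priori) against the model with a single
#' shared inclusion fraction. The Bayes factor is the ratio of marginal
#' likelihoods,
#' \deqn{BF = \frac{m(D_c)\, m(D_t)}{\int_0^1 L_c(\psi) L_t(\psi)\, d\psi},}
#' computed by grid integration in log space. A BF of 5 means the data are
#' five times more likely under differential splicing than under a common
#' PSI. Delta PSI is the difference of the two posterior means
#' (treated minus control).
#'
#' @param counts_control,counts_treated lists or one-row data.frames with
#'   `n_inc`, `n_exc`, `n_shared` for each condition (replicates pooled).
#' @param eff effective sizes for the event (shared across conditions).
#' @param bf_min,dpsi_min call thresholds; an event passes when
#'   `BF > bf_min` and `|delta psi| > dpsi_min`.
#' @param n_grid number of grid points.
#' @return one-row data.frame: `psi_control`, `ci_lo_control`,
#'   `ci_hi_control`, `psi_treated`, `ci_lo_treated`, `ci_hi_treated`,
#'   `delta_psi`, `bayes_factor`, `log_bf`, `passes`.
#' @export
bayes_factor <- function(counts_control, counts_treated, eff,
                         bf_min = 5, dpsi_min = 0.05, n_grid = 1001L) {
  post_c <- psi_posterior(counts_control$n_inc, counts_control$n_exc,
                          counts_control$n_shared, eff, n_grid)
  post_t <- psi_posterior(counts_treated$n_inc, counts_treated$n_exc,
                          counts_treated$n_shared, eff, n_grid)
  g <- .psi_grid(n_grid)
  ll_c <- loglik_psi(g$psi, counts_control$n_inc, counts_control$n_exc,
                     counts_control$n_shared, eff)
  ll_t <- loglik_psi(g$psi, counts_treated$n_inc, counts_treated$n_exc,
                     counts_treated$n_shared, eff)
  log_m0 <- logsumexp(ll_c + ll_t + g$logw)
  log_bf <- post_c$log_marginal + post_t$log_marginal - log_m0
  dpsi <- post_t$mean - post_c$mean
  bf <- exp(log_bf)
  data.frame(psi_control = post_c$mean,
             ci_lo_control = post_c$ci[1], ci_hi_control = post_c$ci[2],
             psi_treated = post_t$mean,
             ci_lo_treated = post_t$ci[1], ci_hi_treated = post_t$ci[2],
             delta_psi = dpsi, bayes_factor = bf, log_bf = log_bf,
             passes = passes_call(bf, dpsi, bf_min, dpsi_min))
}

#' Differential-splicing call rule
#'
#' An event is called differentially spliced when its Bayes factor exceeds
#' `bf_min` AND the absolute difference of posterior-mean PSI exceeds
#' `dpsi_min` (defaults 5 and 0.05). Both inequalities are strict.
#'
#' @param bf Bayes factor(s).
#' @param dpsi delta PSI value(s).
#' @param bf_min,dpsi_min thresholds.
#' @return logical vector.
#' @export
passes_call <- function(bf, dpsi, bf_min = 5, dpsi_min = 0.05) {
  bf > bf_min & abs(dpsi) > dpsi_min
}

#' Call differential splicing across an event set
#'
#' Pools replicate counts per condition (the default inference mode),
#' computes per-event PSI posteriors and Bayes factors, applies the call
#' thresholds, and tallies passing calls by sign of delta PSI and by event
#' type. Untestable events (zero inclusion- or exclusion-specific
#' effective size) are skipped with a logged reason.
#'
#' @param counts data.frame with columns `event_id`, `condition`,
#'   `replicate`, `n_inc`, `n_exc`, `n_shared`.
#' @param eff_table data.frame from [effective_sizes_table()].
#' @param conditions two condition labels, reference first.
#' @param bf_min,dpsi_min call thresholds.
#' @param n_grid posterior grid size.
#' @return list of class `splicing_calls`: `calls` (one row per testable
#'   event), `skipped` (event ids and reasons), `summary` (list with
#'   `n_tested`, `n_passing`, `n_up`, `n_down`, `by_type`).
#' @export
call_events <- function(counts, eff_table, conditions = c("control", "treated"),
                        bf_min = 5, dpsi_min = 0.05, n_grid = 1001L) {
  stopifnot(all(c("event_id", "condition", "n_inc", "n_exc", "n_shared") %in%
                  names(counts)))
  if (!all(counts$condition %in% conditions))
    stop("counts contain conditions outside: ", paste(conditions, collapse = ", "))
  pooled <- stats::aggregate(counts[c("n_inc", "n_exc", "n_shared")],
                             by = counts[c("event_id", "condition")], FUN = sum)
  rows <- list(); skipped <- list()
  for (i in seq_len(nrow(eff_table))) {
    eff <- eff_table[i, ]
    id <- eff$event_id
    if (!isTRUE(eff$testable)) {
      skipped[[id]] <- eff$reason
      next
    }
    cc <- pooled[pooled$event_id == id & pooled$condition == conditions[1], ]
    ct <- pooled[pooled$event_id == id & pooled$condition == conditions[2], ]
    if (nrow(cc) != 1L || nrow(ct) != 1L) {
      skipped[[id]] <- "missing counts in one or both conditions"
      next
    }
    call <- bayes_factor(cc, ct, eff, bf_min, dpsi_min, n_grid)
    rows[[id]] <- cbind(data.frame(event_id = id, event_type = eff$event_type,
                                   stringsAsFactors = FALSE), call)
  }
  calls <- if (length(rows)) rbind_rows(rows) else data.frame()
  passing <- if (nrow(calls)) calls[calls$passes, ] else calls
  by_type <- if (nrow(passing))
    as.list(table(factor(passing$event_type,
                         levels = c("cassette", "alt5", "alt3", "retained_intron"))))
  else list(cassette = 0L, alt5 = 0L, alt3 = 0L, retained_intron = 0L)
  summary <- list(
    n_tested = nrow(calls),
    n_passing = nrow(passing),
    n_up = if (nrow(passing)) sum(passing$delta_psi > 0) else 0L,
    n_down = if (nrow(passing)) sum(passing$delta_psi < 0) else 0L,
    by_type = lapply(by_type, as.integer))
  structure(list(calls = calls,
                 skipped = data.frame(event_id = names(skipped),
                                      reason = unlist(skipped, use.names = FALSE),
                                      stringsAsFactors = FALSE),
                 summary = summary),
            class = "splicing_calls")
}

#' @export
print.splicing_calls <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<splicing_calls> %d tested, %d passing (%d up, %d down), %d skipped\n",
              s$n_tested, s$n_passing, s$n_up, s$n_down, nrow(x$skipped)))
  invisible(x)
}
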