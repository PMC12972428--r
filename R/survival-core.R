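#' Negative Cox partial log-likelihood (Breslow ties)
#'
#' Computes \deqn{-\frac{1}{N_{E=1}} \sum_{i: E_i=1} \left( h_i - \log
#' \sum_{j: T_j \ge T_i} e^{h_j} \right)} with the risk set defined by
#' \eqn{T_j \ge T_i}, i.e. Breslow handling of tied event times. The
#' log-sum-exp is stabilized by a max shift. The value is invariant to
#' adding a constant to every `h`.
#'
#' @param h numeric vector of log-risks.
#' @param time event or censoring times (years).
#' @param event binary event indicators.
#' @return scalar negative mean partial log-likelihood.
#' @export
cox_partial_loglik_neg <- function(h, time, event) {
  n <- length(h)
  stopifnot(length(time) == n, length(event) == n)
  ne <- sum(event == 1)
  if (ne == 0) stop("no events: partial likelihood undefined")
  m <- max(h)
  ord <- order(time, decreasing = TRUE)
  cs <- cumsum(exp(h[ord] - m))
  # risk-set sum for each sorted position: all individuals with time >= t,
  # including later ties — take cumsum at the last index of each tie run
  runs <- rle(time[ord])
  last_of_run <- rep(cumsum(runs$lengths), runs$lengths)
  denom_sorted <- log(cs[last_of_run]) + m
  denom <- numeric(n)
  denom[ord] <- denom_sorted
  ev <- event == 1
  -(sum(h[ev] - denom[ev])) / ne
}

# gradient of cox_partial_loglik_neg with respect to h
cox_grad_h <- function(h, time, event) {
  n <- length(h)
  ne <- sum(event == 1)
  if (ne == 0) stop("no events: gradient undefined")
  m <- max(h)
  eh <- exp(h - m)
  ord <- order(time, decreasing = TRUE)
  cs <- cumsum(eh[ord])
  runs <- rle(time[ord])
  last_of_run <- rep(cumsum(runs$lengths), runs$lengths)
  S <- numeric(n)                      # risk-set sum at each subject's time
  S[ord] <- cs[last_of_run]
  # for each j: sum over events k with T_k <= T_j of 1/S_k
  w <- ifelse(event == 1, 1 / S, 0)
  ord2 <- order(time)                  # ascending
  cw <- cumsum(w[ord2])
  runs2 <- rle(time[ord2])
  last2 <- rep(cumsum(runs2$lengths), runs2$lengths)
  A <- numeric(n)
  A[ord2] <- cw[last2]                 # includes ties at T_j (T_k <= T_j)
  (-(event == 1) + eh * A) / ne
}

#' Multi-condition Cox objective with weight decay
#'
#' Averages the per-condition negative partial log-likelihoods over
#' conditions and adds an L2 penalty on the model parameters:
#' \eqn{l = \frac{1}{|D|}\sum_d g^d + \lambda \lVert\theta\rVert_2^2}.
#' Conditions without events in the evaluated rows are excluded from the
#' mean with a warning.
#'
#' @param h_matrix numeric matrix of log-risks, individuals x conditions;
#'   columns must align with `outcome` conditions.
#' @param outcome an `outcome_table` (or list with `time`/`event`
#'   matrices).
#' @param weight_norm_sq squared L2 norm of the parameters.
#' @param lam weight decay coefficient \eqn{\lambda \ge 0}.
#' @param rows optional row subset to evaluate.
#' @return object of class `objective_value`: `g` (named per-condition
#'   values), `l`, `weight_penalty`, `skipped` (eventless conditions).
#' @export
multi_disease_objective <- function(h_matrix, outcome, weight_norm_sq = 0,
                                    lam = 0, rows = NULL) {
  stopifnot(lam >= 0, ncol(h_matrix) == ncol(outcome$time))
  if (is.null(rows)) rows <- seq_len(nrow(h_matrix))
  D <- ncol(h_matrix)
  cond <- colnames(outcome$time)
  if (is.null(cond)) cond <- paste0("cond_", seq_len(D))
  g <- stats::setNames(rep(NA_real_, D), cond)
  for (d in seq_len(D)) {
    ev <- outcome$event[rows, d]
    if (sum(ev == 1) == 0) next
    g[d] <- cox_partial_loglik_neg(h_matrix[rows, d],
                                   outcome$time[rows, d], ev)
  }
  skipped <- cond[is.na(g)]
  if (length(skipped) == D) stop("all conditions are eventless")
  if (length(skipped)) {
    warning("eventless condition(s) excluded from objective: ",
            paste(skipped, collapse = ", "))
  }
  pen <- lam * weight_norm_sq
  structure(list(g = g, l = mean(g, na.rm = TRUE) + pen,
                 weight_penalty = pen, skipped = skipped),
            class = "objective_value")
}

cindex_counts <- function(h, time, event) {
  n <- length(h)
  conc <- tied <- comp <- 0
  for (i in which(event == 1)) {
    # comparable: j survives past T_i, or is censored exactly at T_i;
    # tied event times (both events) are excluded
    mask <- (time > time[i]) | (time == time[i] & event == 0)
    mask[i] <- FALSE
    if (!any(mask)) next
    conc <- conc + sum(h[i] > h[mask])
    tied <- tied + sum(h[i] == h[mask])
    comp <- comp + sum(mask)
  }
  c(concordant = conc, tied = tied, comparable = comp)
}

#' Harrell's concordance index
#'
#' The probability that of a comparable pair, the individual with the
#' higher predicted log-risk experiences the event first. Comparable pairs
#' are (i, j) with \eqn{T_i < T_j} and \eqn{E_i = 1}, plus tied-time pairs
#' where only i had the event; tied-time pairs with two events are
#' excluded. Tied scores count one half.
#'
#' @param h predicted log-risks.
#' @param time event/censoring times.
#' @param event binary event indicators.
#' @return object of class `concordance_result`: `c_index`, `concordant`,
#'   `tied`, `comparable`.
#' @export
harrell_cindex <- function(h, time, event) {
  stopifnot(length(h) == length(time), length(h) == length(event))
  ct <- cindex_counts(h, time, event)
  if (ct["comparable"] == 0) stop("no comparable pairs")
  structure(list(c_index = unname((ct["concordant"] + 0.5 * ct["tied"]) /
                                    ct["comparable"]),
                 concordant = unname(ct["concordant"]),
                 tied = unname(ct["tied"]),
                 comparable = unname(ct["comparable"])),
            class = "concordance_result")
}

#' Batched concordance index
#'
#' Partitions individuals into seeded batches, accumulates concordant /
#' tied / comparable counts within each batch, and sums the counts before
#' forming the final ratio (default), so the statistic degrades gracefully:
#' with `batch_size >= n` it equals [harrell_cindex()] exactly. Set
#' `aggregate = "ratio_mean"` to average per-batch ratios instead.
#'
#' @inheritParams harrell_cindex
#' @param batch_size batch size (default 2048).
#' @param seed seed for the batch permutation.
#' @param aggregate `"counts"` (default) or `"ratio_mean"`.
#' @return a `concordance_result` (for `"ratio_mean"`, counts are summed
#'   but `c_index` is the mean of per-batch ratios).
#' @export
batched_cindex <- function(h, time, event, batch_size = 2048L, seed = 1L,
                           aggregate = c("counts", "ratio_mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(batch_size >= 2)
  n <- length(h)
  perm <- local({set.seed(seed); sample.int(n)})
  starts <- seq(1L, n, by = batch_size)
  tot <- c(concordant = 0, tied = 0, comparable = 0)
  ratios <- c()
  for (s in starts) {
    idx <- perm[s:min(s + batch_size - 1L, n)]
    if (sum(event[idx]) == 0) next    # eventless batch: zero counts
    ct <- cindex_counts(h[idx], time[idx], event[idx])
    tot <- tot + ct
    if (ct["comparable"] > 0) {
      ratios <- c(ratios, (ct["concordant"] + 0.5 * ct["tied"]) /
                    ct["comparable"])
    }
  }
  if (tot["comparable"] == 0) stop("no comparable pairs in any batch")
  ci <- if (aggregate == "counts") {
    (tot["concordant"] + 0.5 * tot["tied"]) / tot["comparable"]
  } else mean(ratios)
  structure(list(c_index = unname(ci),
                 concordant = unname(tot["concordant"]),
                 tied = unname(tot["tied"]),
                 comparable = unname(tot["comparable"])),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("C-index %.4f (%d concordant, %d tied, %d comparable)\n",
              x$c_index, x$concordant, x$tied, x$comparable))
  invisible(x)
}

#' Kaplan-Meier product-limit estimate
#'
#' Right-continuous step estimate \eqn{S(t) = \prod_{t_k \le t}
#' (1 - d_k / n_k)} with \eqn{S(0) = 1}, computed via
#' [survival::survfit()].
#'
#' @param time nonnegative event/censoring times.
#' @param event binary event indicators.
#' @return data frame with `time` (distinct event times), `surv`,
#'   `n_risk`, `n_event`.
#' @export
kaplan_meier <- function(time, event) {
  if (any(time < 0)) stop("negative times")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- fit$n.event > 0
  data.frame(time = fit$time[keep], surv = fit$surv[keep],
             n_risk = fit$n.risk[keep], n_event = fit$n.event[keep])
}

#' K-group log-rank test
#'
#' Standard log-rank chi-square with k-1 degrees of freedom, via
#' [survival::survdiff()].
#'
#' @param time event/censoring times.
#' @param event binary event indicators.
#' @param group group labels (at least two non-empty groups).
#' @return list with `statistic`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(droplevels(as.factor(group)))
  k <- nlevels(group)
  if (k < 2) stop("log-rank test requires at least two groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(statistic = unname(sd$chisq), df = k - 1L,
       p = stats::pchisq(sd$chisq, df = k - 1L, lower.tail = FALSE))
}
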