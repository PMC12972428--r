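#' Specification of one prognostic disease-pair analysis
#'
#' Prognostic models take the predicted risk quartile of an input
#' condition A, measured at the assessment baseline, as exposure for the
#' hazard of a first diagnosis of an outcome condition B within a fixed
#' horizon. Unlike the onset model (birth baseline, years), these are
#' conventional Cox fits: baseline is the assessment time and follow-up is
#' in months.
#'
#' @param condition_a input condition (exposure quartiles).
#' @param condition_b outcome condition.
#' @param exposure `"quartile"` (Q2-Q4 dummies, Q1 reference) or
#'   `"binary"` (above vs below median, below as reference).
#' @param adjustment `"primary"` (demographic covariates) or
#'   `"secondary"` (demographic plus basic body covariates).
#' @param horizon_months event horizon; later events are censored
#'   (default 120).
#' @param min_uncensored minimum post-baseline events for a pair to be
#'   analyzed (default 50).
#' @param sex_restriction if more than this fraction of events falls in
#'   one sex, the analysis keeps that sex only (default 0.75).
#' @param ties tie handling for the Cox fit, `"efron"` (default, suited
#'   to months-scale ties) or `"breslow"`.
#' @return object of class `pair_spec`.
#' @export
pair_spec <- function(condition_a, condition_b,
                      exposure = c("quartile", "binary"),
                      adjustment = c("primary", "secondary"),
                      horizon_months = 120, min_uncensored = 50L,
                      sex_restriction = 0.75,
                      ties = c("efron", "breslow")) {
  stopifnot(horizon_months > 0, sex_restriction > 0, sex_restriction < 1)
  structure(list(condition_a = condition_a, condition_b = condition_b,
                 exposure = match.arg(exposure),
                 adjustment = match.arg(adjustment),
                 horizon_months = horizon_months,
                 min_uncensored = as.integer(min_uncensored),
                 sex_restriction = sex_restriction,
                 ties = match.arg(ties)),
            class = "pair_spec")
}

#' Build the analysis table for one disease pair
#'
#' Time is months from assessment to the first diagnosis of condition B,
#' administratively censored at the horizon. Individuals already
#' diagnosed with B at assessment are excluded (the same rule applies on
#' the diagonal A == B). If events allocate more than the sex-restriction
#' fraction to one sex, only the dominant sex is kept. Pairs with fewer
#' post-baseline events than `min_uncensored` are skipped with a reason.
#'
#' @param cohort a `cohort`.
#' @param outcomes an `outcome_table` with birth baseline (ages in
#'   years).
#' @param quartiles integer exposure matrix (quartiles or median bins)
#'   for condition A.
#' @param spec a `pair_spec`.
#' @return list with `table` (data frame: `months`, `event`, `exposure`,
#'   covariates), `skipped` (`FALSE` or a reason string), `n`, `events`.
#' @export
prepare_pair_dataset <- function(cohort, outcomes, quartiles, spec) {
  stopifnot(inherits(spec, "pair_spec"),
            outcomes$baseline == "birth",
            spec$condition_a %in% colnames(quartiles),
            spec$condition_b %in% colnames(outcomes$time))
  assess <- cohort$assessment_age
  tb <- outcomes$time[, spec$condition_b]
  eb <- outcomes$event[, spec$condition_b]

  pre <- eb == 1 & tb <= assess         # pre-existing diagnosis of B
  gone <- eb == 0 & tb <= assess        # censored before baseline
  keep <- !(pre | gone)

  months <- (tb - assess) * 12
  event <- eb
  over <- months > spec$horizon_months
  event[over] <- 0L
  months[over] <- spec$horizon_months

  df <- data.frame(months = months, event = event,
                   exposure = quartiles[, spec$condition_a],
                   sex = cohort$sex,
                   stringsAsFactors = FALSE)[keep, , drop = FALSE]

  demog_cols <- names(cohort$groups)[cohort$groups == "demog"]
  bb_cols <- names(cohort$groups)[cohort$groups == "bb"]
  covs <- demog_cols
  if (spec$adjustment == "secondary") covs <- c(covs, bb_cols)
  df <- cbind(df, as.data.frame(cohort$traits[keep, covs, drop = FALSE]))

  # sex restriction on event allocation
  ev_by_sex <- table(df$sex[df$event == 1])
  if (length(ev_by_sex) > 1 && sum(ev_by_sex) > 0) {
    frac <- max(ev_by_sex) / sum(ev_by_sex)
    if (frac > spec$sex_restriction) {
      dominant <- names(ev_by_sex)[which.max(ev_by_sex)]
      df <- df[df$sex == dominant, , drop = FALSE]
    }
  }

  n_events <- sum(df$event == 1)
  skipped <- FALSE
  if (n_events < spec$min_uncensored) {
    skipped <- sprintf("only %d uncensored individuals (< %d) for %s -> %s",
                       n_events, spec$min_uncensored,
                       spec$condition_a, spec$condition_b)
  }
  df$exposure <- factor(df$exposure)
  list(table = df, skipped = skipped, n = nrow(df), events = n_events)
}

#' Fit the adjusted prognostic Cox model for one pair
#'
#' Proportional-hazards fit by Newton-type maximization of the partial
#' likelihood via [survival::coxph()], with the exposure bins entered as
#' dummies against the lowest bin. Constant covariates are dropped before
#' fitting. Non-convergence or separation is flagged in the result, not
#' raised.
#'
#' @param table analysis table from [prepare_pair_dataset()].
#' @param spec a `pair_spec`.
#' @return object of class `prognostic_result`: `coefs` (term, hr,
#'   ci_lo, ci_hi, p), `fit`, `n`, `events`, `converged`, and
#'   `q_top_term` naming the top-bin exposure coefficient.
#' @export
fit_cox_adjusted <- function(table, spec) {
  stopifnot(sum(table$event == 1) >= 1)
  covs <- setdiff(colnames(table), c("months", "event", "exposure"))
  keep <- vapply(covs, function(v) length(unique(table[[v]])) > 1L,
                 logical(1))
  covs <- covs[keep]
  fml <- stats::reformulate(c("exposure", covs),
                            response = "survival::Surv(months, event)")
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = table, ties = spec$ties),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  co <- sm$coefficients
  ci <- sm$conf.int
  coefs <- data.frame(term = rownames(co),
                      coef = co[, "coef"],
                      hr = co[, "exp(coef)"],
                      se = co[, "se(coef)"],
                      ci_lo = ci[, "lower .95"],
                      ci_hi = ci[, "upper .95"],
                      p = co[, "Pr(>|z|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
  top_level <- utils::tail(levels(table$exposure), 1)
  structure(list(coefs = coefs, fit = fit, n = nrow(table),
                 events = sum(table$event == 1), converged = converged,
                 q_top_term = paste0("exposure", top_level)),
            class = "prognostic_result")
}

#' Schoenfeld residual proportional-hazards diagnostics
#'
#' Scaled Schoenfeld residuals correlated against a transform of event
#' time (Kaplan-Meier transform by default) via [survival::cox.zph()],
#' giving a chi-square p-value per covariate and a global test. With
#' fewer than two events the test is undefined and a flagged empty
#' result is returned.
#'
#' @param result a `prognostic_result` (or a `coxph` fit).
#' @param transform time transform: `"km"` (default), `"identity"` or
#'   `"rank"`.
#' @return data frame with `term`, `chisq`, `df`, `p` (last row
#'   `GLOBAL`), or `NULL` with attribute `flagged` when undefined.
#' @export
schoenfeld_test <- function(result, transform = c("km", "identity", "rank")) {
  transform <- match.arg(transform)
  fit <- if (inherits(result, "prognostic_result")) result$fit else result
  if (fit$nevent < 2) {
    out <- NULL
    attr(out, "flagged") <- "fewer than 2 events"
    return(out)
  }
  zp <- survival::cox.zph(fit, transform = transform)
  tab <- as.data.frame(zp$table)
  data.frame(term = rownames(tab), chisq = tab$chisq, df = tab$df,
             p = tab$p, row.names = NULL, stringsAsFactors = FALSE)
}

#' Run adjusted prognostic Cox models over all condition pairs
#'
#' One fit per (input A, outcome B) pair. For each pair the primary
#' (demographic) adjustment is fitted with Schoenfeld diagnostics, and a
#' secondary fit (demographic + basic body) probes robustness of the
#' top-bin coefficient. Pair-level failures and skips are logged and the
#' run continues. Because the intended multiplicity family for the
#' Bonferroni level is an analysis choice, it is an explicit argument;
#' both the planned-fit count and the user family are reported.
#'
#' @param cohort a `cohort`.
#' @param outcomes birth-baseline `outcome_table`.
#' @param quartiles integer exposure matrix.
#' @param conditions_in input conditions (columns of `quartiles`).
#' @param conditions_out outcome conditions.
#' @param spec_template `pair_spec`-like settings applied to every pair.
#' @param bonferroni_family family size for the corrected level; default
#'   the number of planned fits.
#' @param alpha significance level (default 0.05).
#' @return object of class `prognostic_matrix`: `planned`, `results`
#'   (per-pair list), `summary` (counts), `skips`.
#' @export
run_all_pairs <- function(cohort, outcomes, quartiles,
                          conditions_in = colnames(quartiles),
                          conditions_out = outcomes$conditions,
                          spec_template = NULL,
                          bonferroni_family = NULL, alpha = 0.05) {
  planned <- length(conditions_in) * length(conditions_out)
  if (is.null(bonferroni_family)) bonferroni_family <- planned
  thr <- bonferroni_threshold(alpha, bonferroni_family)
  results <- list()
  skips <- list()
  for (a in conditions_in) {
    for (b in conditions_out) {
      spec <- pair_spec(a, b)
      if (!is.null(spec_template)) {
        for (f in intersect(names(spec_template), names(spec))) {
          spec[[f]] <- spec_template[[f]]
        }
      }
      key <- paste(a, b, sep = "->")
      res <- tryCatch({
        prep <- prepare_pair_dataset(cohort, outcomes, quartiles, spec)
        if (!isFALSE(prep$skipped)) {
          skips[[key]] <- prep$skipped
          NULL
        } else {
          fit <- fit_cox_adjusted(prep$table, spec)
          sch <- schoenfeld_test(fit)
          spec2 <- spec; spec2$adjustment <- "secondary"
          prep2 <- prepare_pair_dataset(cohort, outcomes, quartiles, spec2)
          fit2 <- if (isFALSE(prep2$skipped)) {
            fit_cox_adjusted(prep2$table, spec2)
          } else NULL
          qrow <- fit$coefs[fit$coefs$term == fit$q_top_term, ]
          q2row <- if (!is.null(fit2)) {
            fit2$coefs[fit2$coefs$term == fit2$q_top_term, ]
          } else NULL
          ph_ok <- !is.null(sch) && all(sch$p > 0.05, na.rm = TRUE)
          list(a = a, b = b, n = fit$n, events = fit$events,
               hr = qrow$hr, log_hr = qrow$coef, se = qrow$se,
               p = qrow$p, converged = fit$converged,
               schoenfeld = sch, ph_ok = ph_ok,
               significant_primary = is.finite(qrow$p) && qrow$p < alpha,
               significant_bonferroni = is.finite(qrow$p) && qrow$p <= thr,
               robust_secondary = !is.null(q2row) &&
                 is.finite(q2row$p) && q2row$p < alpha,
               coefs = fit$coefs)
        }
      }, error = function(e) {
        skips[[key]] <<- conditionMessage(e)
        NULL
      })
      if (!is.null(res)) results[[key]] <- res
    }
  }
  fitted <- length(results)
  sig <- vapply(results, `[[`, logical(1), "significant_primary")
  sigb <- vapply(results, `[[`, logical(1), "significant_bonferroni")
  ph <- vapply(results, `[[`, logical(1), "ph_ok")
  rob <- vapply(results, `[[`, logical(1), "robust_secondary")
  summary <- data.frame(planned = planned, fitted = fitted,
                        skipped = length(skips),
                        significant_alpha = sum(sig),
                        significant_bonferroni = sum(sigb),
                        ph_pass_fraction = if (fitted) mean(ph) else NA_real_,
                        robust_secondary = sum(rob & sig),
                        bonferroni_family = bonferroni_family,
                        bonferroni_level = thr)
  structure(list(planned = planned, results = results, summary = summary,
                 skips = skips),
            class = "prognostic_matrix")
}

#' Tabulate a prognostic run as one row per pair
#'
#' Renders the pair matrix with the masking semantics used for display:
#' `masked` marks pairs insignificant after primary adjustment or with a
#' proportional-hazards violation; `robust` marks pairs still significant
#' under secondary adjustment.
#'
#' @param x a `prognostic_matrix`.
#' @return data frame, one row per fitted pair.
#' @export
prognostic_table <- function(x) {
  stopifnot(inherits(x, "prognostic_matrix"))
  do.call(rbind, lapply(x$results, function(r) {
    data.frame(a = r$a, b = r$b, n = r$n, events = r$events,
               log_hr = r$log_hr, hr = r$hr, se = r$se, p = r$p,
               ph_ok = r$ph_ok,
               masked = !(r$significant_bonferroni && r$ph_ok),
               robust = r$robust_secondary,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.prognostic_matrix <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<prognostic_matrix> %d planned, %d fitted, %d skipped; ",
                     "%d significant at alpha, %d at Bonferroni level %.3g\n"),
              s$planned, s$fitted, s$skipped, s$significant_alpha,
              s$significant_bonferroni, s$bonferroni_level))
  invisible(x)
}
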