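toy_cohort <- function(n, assess = 50, seed = 1) {
  set.seed(seed)
  traits <- cbind(demog_1 = rnorm(n), bb_1 = rnorm(n))
  structure(list(ids = sprintf("i%04d", 1:n),
                 sex = sample(c("female", "male"), n, TRUE),
                 center = rep("a", n),
                 statin_user = rep(FALSE, n),
                 assessment_age = rep(assess, length.out = n),
                 traits = traits,
                 groups = c(demog_1 = "demog", bb_1 = "bb"),
                 meas_age = cbind(bb_1 = rep(assess, n))),
            class = "cohort")
}

toy_outcomes <- function(time, event, cond = "B") {
  structure(list(ids = sprintf("i%04d", seq_along(time)),
                 time = matrix(time, ncol = 1, dimnames = list(NULL, cond)),
                 event = matrix(as.integer(event), ncol = 1,
                                dimnames = list(NULL, cond)),
                 conditions = cond, baseline = "birth"),
            class = "outcome_table")
}

test_that("pair datasets exclude pre-baseline diagnoses and censor at the horizon", {
  n <- 200
  co <- toy_cohort(n, assess = 50)
  set.seed(2)
  tt <- 50 + rexp(n, 0.2)         # ages at diagnosis, after assessment
  ev <- rep(1L, n)
  tt[1] <- 49; ev[1] <- 1L        # diagnosed one year before assessment
  tt[2] <- 61; ev[2] <- 1L        # event 11 years out: beyond the horizon
  out <- toy_outcomes(tt, ev)
  q <- matrix(sample(1:4, n, TRUE), ncol = 1, dimnames = list(NULL, "A"))
  prep <- prepare_pair_dataset(co, out, q, pair_spec("A", "B"))
  expect_equal(prep$n, n - 1)                 # pre-existing diagnosis removed
  row2 <- prep$table[1, ]                     # individual 2 is now first
  expect_equal(row2$months, 120)
  expect_equal(row2$event, 0L)
})

test_that("pairs with fewer than the minimum uncensored individuals are skipped", {
  n <- 300
  co <- toy_cohort(n, assess = 50)
  mk <- function(k) {
    ev <- c(rep(1L, k), rep(0L, n - k))
    tt <- c(51 + (seq_len(k) %% 5), rep(80, n - k))
    toy_outcomes(tt, ev)
  }
  q <- matrix(rep(1:4, length.out = n), ncol = 1, dimnames = list(NULL, "A"))
  p49 <- prepare_pair_dataset(co, mk(49), q, pair_spec("A", "B"))
  expect_match(p49$skipped, "49 uncensored")
  p50 <- prepare_pair_dataset(co, mk(50), q, pair_spec("A", "B"))
  expect_false(isTRUE(p50$skipped != FALSE))
})

test_that("sex-dominated outcomes are restricted to the dominant sex", {
  n <- 400
  co <- toy_cohort(n, assess = 50, seed = 3)
  set.seed(3)
  ev <- rep(0L, n)
  fem <- which(co$sex == "female")
  ev[fem[1:80]] <- 1L                       # all events female
  ev[which(co$sex == "male")[1:5]] <- 1L    # a few male events (< 25%)
  tt <- ifelse(ev == 1, 51 + runif(n, 0, 8), 80)
  q <- matrix(sample(1:4, n, TRUE), ncol = 1, dimnames = list(NULL, "A"))
  prep <- prepare_pair_dataset(co, toy_outcomes(tt, ev), q,
                               pair_spec("A", "B"))
  expect_true(all(prep$table$sex == "female"))
})

test_that("a four-subject fit matches the analytic partial-likelihood maximizer", {
  tab <- data.frame(months = c(1, 2, 3, 4), event = c(1L, 1L, 0L, 0L),
                    exposure = factor(c(2, 1, 2, 1)))
  fit <- fit_cox_adjusted(tab, pair_spec("A", "B"))
  # hand solution: d/db [b - log(2e^b+2) - log(e^b+2)] = 0 at e^b = sqrt(2)
  expect_equal(fit$coefs$coef[fit$coefs$term == "exposure2"],
               log(sqrt(2)), tolerance = 1e-6)
})

test_that("null exposures give hazard ratios near one", {
  set.seed(4)
  n <- 2000
  tab <- data.frame(months = rexp(n, 0.02), event = 1L,
                    exposure = factor(sample(1:4, n, TRUE)),
                    demog_1 = rnorm(n))
  tab$event[tab$months > 120] <- 0L
  tab$months <- pmin(tab$months, 120)
  fit <- fit_cox_adjusted(tab, pair_spec("A", "B"))
  q4 <- fit$coefs[fit$coefs$term == "exposure4", ]
  expect_lt(abs(q4$coef), 3 * q4$se)
})

test_that("a planted threefold top-quartile hazard is recovered within 3 SE", {
  set.seed(5)
  n <- 5000
  q <- sample(1:4, n, TRUE)
  lam <- 0.01 * ifelse(q == 4, 3, 1)
  months <- rexp(n, lam)
  event <- as.integer(months <= 120)
  months <- pmin(months, 120)
  tab <- data.frame(months = months, event = event, exposure = factor(q),
                    demog_1 = rnorm(n))
  fit <- fit_cox_adjusted(tab, pair_spec("A", "B"))
  q4 <- fit$coefs[fit$coefs$term == "exposure4", ]
  expect_lt(abs(q4$coef - log(3)), 3 * q4$se)
})

test_that("hazard ratios are invariant to affine rescaling of adjustment covariates", {
  set.seed(6)
  n <- 800
  tab <- data.frame(months = rexp(n, 0.03), event = rbinom(n, 1, 0.8),
                    exposure = factor(sample(1:4, n, TRUE)),
                    demog_1 = rnorm(n))
  f1 <- fit_cox_adjusted(tab, pair_spec("A", "B"))
  tab2 <- tab; tab2$demog_1 <- 1e3 * tab$demog_1 + 5
  f2 <- fit_cox_adjusted(tab2, pair_spec("A", "B"))
  h1 <- f1$coefs$hr[f1$coefs$term == "exposure4"]
  h2 <- f2$coefs$hr[f2$coefs$term == "exposure4"]
  expect_equal(h1, h2, tolerance = 1e-6)
})

test_that("Wald interval coverage for the top-quartile effect is nominal", {
  set.seed(7)
  covered <- 0
  reps <- 200
  for (r in seq_len(reps)) {
    n <- 300
    q <- sample(1:4, n, TRUE)
    months <- rexp(n, 0.02 * exp(0.5 * (q == 4)))
    event <- as.integer(months <= 120)
    months <- pmin(months, 120)
    tab <- data.frame(months = months, event = event, exposure = factor(q))
    fit <- fit_cox_adjusted(tab, pair_spec("A", "B"))
    q4 <- fit$coefs[fit$coefs$term == "exposure4", ]
    covered <- covered +
      (log(q4$ci_lo) <= 0.5 && 0.5 <= log(q4$ci_hi))
  }
  # binomial 99% bounds around 0.95 with 200 replicates
  expect_gte(covered / reps, 0.91)
  expect_lte(covered / reps, 0.99)
})

test_that("constant covariates are dropped before Schoenfeld diagnostics", {
  set.seed(8)
  n <- 400
  tab <- data.frame(months = rexp(n, 0.03), event = rbinom(n, 1, 0.7),
                    exposure = factor(sample(1:2, n, TRUE)),
                    demog_1 = rnorm(n), bb_1 = 1)
  fit <- fit_cox_adjusted(tab, pair_spec("A", "B"))
  sch <- schoenfeld_test(fit)
  expect_false("bb_1" %in% sch$term)
  expect_true("GLOBAL" %in% sch$term)
})

test_that("Schoenfeld diagnostics detect a crossover hazard with high power", {
  rejected <- 0
  set.seed(9)
  for (r in 1:10) {
    n <- 2000
    x <- rbinom(n, 1, 0.5)
    # piecewise hazard: effect +1 before t=1, -1 after; rates keep both
    # groups at risk across the reversal (a detectable crossover)
    e <- rexp(n)
    h1 <- 0.4 * exp(x); h2 <- 0.4 * exp(-x)
    tt <- ifelse(e < h1, e / h1, 1 + (e - h1) / h2)
    ev <- as.integer(tt <= 5); tt <- pmin(tt, 5)
    tab <- data.frame(months = tt, event = ev,
                      exposure = factor(x + 1))
    fit <- fit_cox_adjusted(tab, pair_spec("A", "B"))
    sch <- schoenfeld_test(fit)
    rejected <- rejected + (sch$p[sch$term == "GLOBAL"] < 0.05)
  }
  expect_gte(rejected, 8)
})

test_that("the all-pairs run fits every viable pair and summarizes counts", {
  cfg <- generator_config(n_individuals = 4000, n_conditions = 3,
                          n_latent = 2, cluster_strength = 0.6, seed = 15)
  sim <- generate_cohort(cfg)
  split <- make_splits(sim$cohort, "ext", seed = 15)
  bins <- fit_quartile_bins(sim$truth$eta, sim$cohort$sex, split)
  q <- assign_quartiles(sim$truth$eta, sim$cohort$sex, bins)
  res <- run_all_pairs(sim$cohort, sim$outcomes, q)
  expect_equal(res$planned, 9)
  expect_equal(length(res$results) + length(res$skips), 9)
  tab <- prognostic_table(res)
  expect_true(all(tab$hr > 0))
  expect_true(all(c("masked", "robust") %in% colnames(tab)))

  # risk quartiles from the true log-risk must be prognostic on the diagonal
  diag_rows <- tab[tab$a == tab$b, ]
  expect_true(all(diag_rows$log_hr > 0))
})

test_that("a signal-free cohort yields no Bonferroni-significant pairs", {
  cfg <- generator_config(n_individuals = 3000, n_conditions = 3,
                          n_latent = 2,
                          true_weights = matrix(0, 3, 15),
                          cluster_strength = 0, seed = 16)
  sim <- generate_cohort(cfg)
  set.seed(16)
  q <- matrix(sample(1:4, 3000 * 3, TRUE), 3000,
              dimnames = list(NULL, sim$outcomes$conditions))
  res <- run_all_pairs(sim$cohort, sim$outcomes, q)
  expect_lte(res$summary$significant_bonferroni, 1)
})
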