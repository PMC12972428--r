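#' Configuration for the synthetic cohort generator
#'
#' Builds a validated configuration for [generate_cohort()]. The generator
#' draws per-individual traits from a small set of latent factors, assigns
#' each condition to one factor, and simulates age at first diagnosis from a
#' Weibull proportional-hazards law so that the true log-risk
#' \eqn{\eta_{i,d} = w_d \cdot x_i + \gamma z_{i,c(d)}} is known exactly.
#' Weibull PH is used because it satisfies the proportional-hazards
#' assumption by construction, making it the correct null for Schoenfeld
#' diagnostics and a fair target for Cox-based recovery.
#'
#' @param n_individuals number of individuals to simulate.
#' @param n_conditions number of disease conditions (default 12).
#' @param n_latent number of latent cluster factors.
#' @param cluster_map integer vector of length `n_conditions` mapping each
#'   condition to a latent factor in `1:n_latent`; default round-robin.
#' @param trait_group_sizes named integer vector over the five trait groups
#'   `demog`, `bb`, `bbc`, `sbc`, `blood`. The `sbc` entry counts tissues;
#'   each tissue contributes `sbc_slices` spatial columns.
#' @param sbc_slices number of vertical slices per spatial tissue (default
#'   370, the resolution of neck-to-knee composition profiles).
#' @param weibull_shape per-condition Weibull shape \eqn{\kappa_d > 0}
#'   (recycled). Default 4, giving the sharply age-increasing hazard typical
#'   of age-associated disease.
#' @param weibull_scale per-condition Weibull rate \eqn{\lambda_{0,d} > 0}
#'   in events per year^shape (recycled). Default tuned so the baseline
#'   median onset age is about 70 years.
#' @param true_weights `n_conditions x n_traits` matrix of true linear risk
#'   weights; default sparse random weights drawn from the seed.
#' @param cluster_strength latent factor loading \eqn{\gamma \ge 0} shared
#'   by conditions mapped to the same factor.
#' @param trait_loading_range range of per-trait loadings on the latent
#'   factors (default `c(0.3, 0.8)`); set to `c(0, 0)` for mutually
#'   independent traits.
#' @param censor_age administrative censoring age in years.
#' @param assessment_age_range length-2 numeric, min and max assessment age.
#' @param statin_fraction fraction of individuals flagged as statin users.
#' @param center_labels assessment center labels; one is external.
#' @param external_center label of the designated external test center.
#' @param round_ages if `TRUE`, onset ages are rounded to whole years to
#'   emulate diagnosis-date granularity and exercise tie handling.
#' @param seed integer RNG seed; identical seeds give identical cohorts.
#'
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_individuals = 1000L,
                             n_conditions = 12L,
                             n_latent = 3L,
                             cluster_map = NULL,
                             trait_group_sizes = c(demog = 2L, bb = 4L,
                                                   bbc = 3L, sbc = 0L,
                                                   blood = 6L),
                             sbc_slices = 370L,
                             weibull_shape = 4,
                             weibull_scale = log(2) / 70^4,
                             true_weights = NULL,
                             cluster_strength = 0.5,
                             trait_loading_range = c(0.3, 0.8),
                             censor_age = 80,
                             assessment_age_range = c(45, 70),
                             statin_fraction = 0.2,
                             center_labels = c("alpha", "beta", "gamma", "ext"),
                             external_center = "ext",
                             round_ages = FALSE,
                             seed = 1L) {
  stopifnot(n_individuals >= 1, n_conditions >= 1, n_latent >= 1)
  groups <- c("demog", "bb", "bbc", "sbc", "blood")
  if (is.null(names(trait_group_sizes)) ||
      !all(names(trait_group_sizes) %in% groups)) {
    stop("trait_group_sizes must be named with groups among: ",
         paste(groups, collapse = ", "))
  }
  sizes <- stats::setNames(integer(5), groups)
  sizes[names(trait_group_sizes)] <- as.integer(trait_group_sizes)
  if (any(sizes < 0)) stop("trait group sizes must be non-negative")

  if (is.null(cluster_map)) {
    cluster_map <- rep_len(seq_len(n_latent), n_conditions)
  }
  cluster_map <- as.integer(cluster_map)
  if (length(cluster_map) != n_conditions ||
      any(cluster_map < 1L | cluster_map > n_latent)) {
    stop("cluster_map must assign every condition to one factor in 1..n_latent")
  }

  shape <- rep_len(weibull_shape, n_conditions)
  scale <- rep_len(weibull_scale, n_conditions)
  bad <- which(!(shape > 0) | !(scale > 0))
  if (length(bad)) {
    stop("non-positive Weibull parameters for condition(s): ",
         paste(bad, collapse = ", "))
  }

  stopifnot(length(assessment_age_range) == 2,
            assessment_age_range[1] < assessment_age_range[2],
            censor_age > assessment_age_range[2],
            statin_fraction >= 0, statin_fraction <= 1,
            external_center %in% center_labels,
            length(trait_loading_range) == 2,
            all(trait_loading_range >= 0), all(trait_loading_range < 1))

  n_traits <- sum(sizes[c("demog", "bb", "bbc", "blood")]) +
    sizes["sbc"] * sbc_slices
  if (!is.null(true_weights)) {
    true_weights <- as.matrix(true_weights)
    if (nrow(true_weights) != n_conditions || ncol(true_weights) != n_traits) {
      stop("true_weights must be ", n_conditions, " x ", n_traits,
           " (conditions x total traits)")
    }
  }

  structure(list(n_individuals = as.integer(n_individuals),
                 n_conditions = as.integer(n_conditions),
                 n_latent = as.integer(n_latent),
                 cluster_map = cluster_map,
                 trait_group_sizes = sizes,
                 sbc_slices = as.integer(sbc_slices),
                 weibull_shape = shape,
                 weibull_scale = scale,
                 true_weights = true_weights,
                 cluster_strength = cluster_strength,
                 trait_loading_range = trait_loading_range,
                 censor_age = censor_age,
                 assessment_age_range = assessment_age_range,
                 statin_fraction = statin_fraction,
                 center_labels = center_labels,
                 external_center = external_center,
                 round_ages = isTRUE(round_ages),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Invert the Weibull proportional-hazards survival function
#'
#' Draws an onset age from hazard \eqn{h(t) = \kappa \lambda_0 t^{\kappa-1}
#' e^\eta} by inverse-CDF: \eqn{T = (-\ln u / (\lambda_0 e^\eta))^{1/\kappa}}.
#' For fixed `u` the returned age is strictly decreasing in `eta`.
#'
#' @param eta true log-risk (vectorized).
#' @param shape Weibull shape \eqn{\kappa > 0}.
#' @param scale Weibull rate \eqn{\lambda_0 > 0} (events per year^shape).
#' @param u uniform quantile strictly inside (0, 1).
#' @return onset age in years, strictly positive.
#' @export
simulate_onset_age <- function(eta, shape, scale, u) {
  if (any(!(shape > 0)) || any(!(scale > 0))) {
    stop("shape and scale must be positive")
  }
  if (any(u <= 0 | u >= 1)) {
    stop("u must lie strictly inside (0, 1)")
  }
  (-log(u) / (scale * exp(eta)))^(1 / shape)
}

trait_names_for <- function(cfg) {
  sizes <- cfg$trait_group_sizes
  nm <- c()
  grp <- c()
  for (g in c("demog", "bb", "bbc")) {
    if (sizes[g] > 0) {
      nm <- c(nm, paste0(g, "_", seq_len(sizes[g])))
      grp <- c(grp, rep(g, sizes[g]))
    }
  }
  if (sizes["sbc"] > 0) {
    for (t in seq_len(sizes["sbc"])) {
      nm <- c(nm, sprintf("sbc%d_slice%03d", t, seq_len(cfg$sbc_slices)))
      grp <- c(grp, rep("sbc", cfg$sbc_slices))
    }
  }
  if (sizes["blood"] > 0) {
    nm <- c(nm, paste0("blood_", seq_len(sizes["blood"])))
    grp <- c(grp, rep("blood", sizes["blood"]))
  }
  list(names = nm, groups = grp)
}

#' Generate a synthetic cohort with known ground-truth log-risk
#'
#' Simulates traits, outcomes and the generating truth under the model of
#' [generator_config()]: latent factors \eqn{z_i \sim N(0, I)}, traits as
#' factor loadings plus independent noise, true log-risk
#' \eqn{\eta_{i,d} = w_d \cdot x_i + \gamma z_{i,c(d)}}, and Weibull-PH onset
#' ages administratively censored at `censor_age`. Spatial (`sbc`) traits are
#' smooth per-tissue slice profiles: a factor loading times a fixed smooth
#' basis over slices plus noise. Pre-baseline diagnoses arise naturally when
#' the simulated onset precedes the assessment age.
#'
#' @param config a `generator_config`.
#' @return a list with elements `cohort` (class `cohort`), `outcomes`
#'   (class `outcome_table`, birth baseline), `registry` (condition
#'   data frame) and `truth` (list: `eta`, `latent`, `uncensored_onset`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_individuals
  D <- cfg$n_conditions
  tn <- trait_names_for(cfg)
  p <- length(tn$names)

  Z <- matrix(stats::rnorm(n * cfg$n_latent), n, cfg$n_latent)

  # loadings: each univariate trait loads on one latent factor; sbc tissues
  # share one loading modulated by a smooth Gaussian bump over slices
  X <- matrix(0, n, p, dimnames = list(NULL, tn$names))
  j <- 1L
  sizes <- cfg$trait_group_sizes
  lr <- cfg$trait_loading_range
  for (g in c("demog", "bb", "bbc")) {
    for (k in seq_len(sizes[g])) {
      f <- 1L + (j - 1L) %% cfg$n_latent
      lam <- stats::runif(1, lr[1], lr[2])
      X[, j] <- lam * Z[, f] + stats::rnorm(n, sd = sqrt(1 - lam^2))
      j <- j + 1L
    }
  }
  if (sizes["sbc"] > 0) {
    s <- seq_len(cfg$sbc_slices)
    for (t in seq_len(sizes["sbc"])) {
      f <- 1L + (t - 1L) %% cfg$n_latent
      centre <- stats::runif(1, 0.3, 0.7) * cfg$sbc_slices
      width <- cfg$sbc_slices / 6
      basis <- exp(-0.5 * ((s - centre) / width)^2)
      lam <- stats::runif(1, lr[1], lr[2])
      prof <- outer(lam * Z[, f], basis) +
        matrix(stats::rnorm(n * cfg$sbc_slices, sd = 0.3), n)
      X[, j:(j + cfg$sbc_slices - 1L)] <- prof
      j <- j + cfg$sbc_slices
    }
  }
  if (sizes["blood"] > 0) {
    for (k in seq_len(sizes["blood"])) {
      f <- 1L + (j - 1L) %% cfg$n_latent
      lam <- stats::runif(1, lr[1], lr[2])
      X[, j] <- lam * Z[, f] + stats::rnorm(n, sd = sqrt(1 - lam^2))
      j <- j + 1L
    }
  }

  W <- cfg$true_weights
  if (is.null(W)) {
    # sparse weights: ~3 informative univariate traits per condition
    W <- matrix(0, D, p)
    univ <- which(tn$groups != "sbc")
    for (d in seq_len(D)) {
      k <- min(3L, length(univ))
      pick <- sample(univ, k)
      W[d, pick] <- stats::rnorm(k, sd = 0.4)
    }
  }

  eta <- X %*% t(W) + cfg$cluster_strength * Z[, cfg$cluster_map, drop = FALSE]
  colnames(eta) <- paste0("cond_", seq_len(D))

  U <- matrix(stats::runif(n * D), n, D)
  U <- pmin(pmax(U, 1e-12), 1 - 1e-12)
  Tlat <- matrix(0, n, D)
  for (d in seq_len(D)) {
    Tlat[, d] <- simulate_onset_age(eta[, d], cfg$weibull_shape[d],
                                    cfg$weibull_scale[d], U[, d])
  }
  if (cfg$round_ages) Tlat <- pmax(round(Tlat), 1)

  event <- (Tlat <= cfg$censor_age) * 1L
  time <- pmin(Tlat, cfg$censor_age)
  cond <- colnames(eta)
  dimnames(time) <- dimnames(event) <- list(NULL, cond)

  sex <- sample(c("female", "male"), n, replace = TRUE)
  center <- sample(cfg$center_labels, n, replace = TRUE)
  statin <- stats::runif(n) < cfg$statin_fraction
  assess <- stats::runif(n, cfg$assessment_age_range[1],
                         cfg$assessment_age_range[2])

  # blood samples precede imaging assessment by about a decade
  meas_cols <- which(tn$groups != "demog")
  meas_age <- matrix(rep(assess, length(meas_cols)), n,
                     dimnames = list(NULL, tn$names[meas_cols]))
  blood_cols <- which(tn$groups[meas_cols] == "blood")
  if (length(blood_cols)) {
    offs <- pmax(stats::rnorm(n, 11, 2), 0)
    meas_age[, blood_cols] <- pmax(meas_age[, blood_cols] - offs, 18)
  }

  ids <- sprintf("ind%06d", seq_len(n))
  cohort <- structure(list(ids = ids,
                           sex = sex,
                           center = center,
                           statin_user = statin,
                           assessment_age = assess,
                           traits = X,
                           groups = stats::setNames(tn$groups, tn$names),
                           meas_age = meas_age),
                      class = "cohort")
  outcomes <- structure(list(ids = ids,
                             time = time,
                             event = event,
                             conditions = cond,
                             baseline = "birth"),
                        class = "outcome_table")
  registry <- data.frame(condition = cond,
                         type = rep_len(c("cardiometabolic", "neuropsychiatric",
                                          "digestive"), D),
                         sex_restriction = "none",
                         stringsAsFactors = FALSE)
  truth <- list(eta = eta, latent = Z, uncensored_onset = Tlat)
  list(cohort = cohort, outcomes = outcomes, registry = registry,
       truth = truth)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d individuals, %d traits (%s)\n",
              length(x$ids), ncol(x$traits),
              paste(sprintf("%s:%d", names(table(x$groups)),
                            as.integer(table(x$groups))), collapse = " ")))
  invisible(x)
}

#' @export
print.outcome_table <- function(x, ...) {
  cat(sprintf("<outcome_table> %d individuals x %d conditions, baseline=%s, %d events\n",
              nrow(x$time), ncol(x$time), x$baseline, sum(x$event)))
  invisible(x)
}
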