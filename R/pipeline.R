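#' Configuration for an end-to-end pipeline run
#'
#' Collects every stage's settings in one validated object, loadable from
#' a YAML file via [read_run_config()]. Either a generator configuration
#' (synthetic run) or paths to a cohort file pair must be supplied.
#'
#' @param generator a `generator_config`, or `NULL` to read files.
#' @param traits_path,outcomes_path,registry_path cohort files when no
#'   generator is given.
#' @param out_dir output directory for artifacts and the manifest.
#' @param test_fraction internal-test fraction for [make_splits()].
#' @param n_folds cross-validation folds.
#' @param arch an `arch_config`; `NULL` derives a default from the data.
#' @param train a `train_config`.
#' @param grid optional hyperparameter grid for [cross_validate()];
#'   `NULL` trains a single configuration on fold 1.
#' @param cindex_threshold condition retention threshold (default 0.6).
#' @param edge_threshold correlation graph edge threshold (default 0.3).
#' @param alpha significance level (default 0.05).
#' @param horizon_months prognostic horizon (default 120).
#' @param min_uncensored prognostic event minimum (default 50).
#' @param sex_restriction prognostic sex-restriction fraction (0.75).
#' @param exclude_statin exclude statin users from correlations.
#' @param prognostic_max_pairs optional cap on the number of input
#'   conditions taken into the prognostic stage (runtime control).
#' @param seed master seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(generator = NULL, traits_path = NULL,
                       outcomes_path = NULL, registry_path = NULL,
                       out_dir = "onsetrisk_run",
                       test_fraction = 0.15, n_folds = 5L,
                       arch = NULL, train = train_config(),
                       grid = NULL,
                       cindex_threshold = 0.6, edge_threshold = 0.3,
                       alpha = 0.05, horizon_months = 120,
                       min_uncensored = 50L, sex_restriction = 0.75,
                       exclude_statin = TRUE,
                       prognostic_max_pairs = NULL, seed = 1L) {
  if (is.null(generator) &&
      (is.null(traits_path) || is.null(outcomes_path) ||
       is.null(registry_path))) {
    stop("either a generator config or the three cohort file paths are required")
  }
  if (!is.null(traits_path)) {
    for (p in c(traits_path, outcomes_path, registry_path)) {
      if (!file.exists(p)) stop("input file does not exist: ", p)
    }
  }
  stopifnot(cindex_threshold >= 0, cindex_threshold <= 1,
            edge_threshold >= -1, edge_threshold <= 1,
            alpha > 0, alpha < 1, horizon_months > 0,
            sex_restriction > 0, sex_restriction < 1)
  structure(list(generator = generator, traits_path = traits_path,
                 outcomes_path = outcomes_path,
                 registry_path = registry_path, out_dir = out_dir,
                 test_fraction = test_fraction, n_folds = as.integer(n_folds),
                 arch = arch, train = train, grid = grid,
                 cindex_threshold = cindex_threshold,
                 edge_threshold = edge_threshold, alpha = alpha,
                 horizon_months = horizon_months,
                 min_uncensored = as.integer(min_uncensored),
                 sex_restriction = sex_restriction,
                 exclude_statin = isTRUE(exclude_statin),
                 prognostic_max_pairs = prognostic_max_pairs,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; top-level keys mirror [run_config()] arguments,
#'   with `generator`, `arch` and `train` given as nested maps.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$generator)) y$generator <- do.call(generator_config, y$generator)
  if (!is.null(y$arch)) y$arch <- do.call(arch_config, y$arch)
  if (!is.null(y$train)) y$train <- do.call(train_config, y$train)
  if (!is.null(y$grid)) y$grid <- as.data.frame(y$grid)
  do.call(run_config, y)
}

write_tab <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: simulate or ingest, split, preprocess
#' (train-val statistics), train (single fold or cross-validated
#' selection), score, quartiles, Kaplan-Meier / log-rank stratification,
#' correlation clustering, prognostic pair models, and saliency.
#' Artifacts are written as delimited tables under `out_dir`, together
#' with a JSON manifest recording seeds, stage metrics and file
#' checksums. Reruns with the same configuration are bit-reproducible
#' for the deterministic stages.
#'
#' @param config a `run_config`.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  # no timestamps in the manifest: same config + seed must hash identically
  manifest <- list(seed = config$seed, stages = list())

  # --- data
  if (!is.null(config$generator)) {
    sim <- generate_cohort(config$generator)
    cohort <- sim$cohort; outcomes <- sim$outcomes
    registry <- sim$registry; truth <- sim$truth
    external <- config$generator$external_center
  } else {
    rd <- read_cohort(config$traits_path, config$outcomes_path,
                      config$registry_path)
    cohort <- rd$cohort; outcomes <- rd$outcomes
    registry <- rd$registry; truth <- NULL
    external <- unique(cohort$center)[length(unique(cohort$center))]
  }
  manifest$stages$data <- list(n = length(cohort$ids),
                               n_conditions = length(outcomes$conditions))

  split <- make_splits(cohort, external, config$test_fraction,
                       config$n_folds, seed = config$seed)
  stats <- fit_preprocess(cohort, split)
  features <- apply_preprocess(cohort, stats)

  arch <- config$arch
  if (is.null(arch)) {
    arch <- arch_config(groups = names(features$blocks),
                        n_conditions = length(outcomes$conditions),
                        k = 32L)
  }
  cfg <- config$train
  cfg$seed <- config$seed

  # --- train (optionally with CV model selection)
  if (!is.null(config$grid) && nrow(config$grid) > 1) {
    cv <- cross_validate(features, outcomes, split, config$grid, arch, cfg)
    if ("k" %in% names(cv$best)) arch$k <- as.integer(cv$best$k)
    if ("dropout" %in% names(cv$best)) arch$dropout <- cv$best$dropout
    if ("lam" %in% names(cv$best)) cfg$lam <- cv$best$lam
    if ("lr" %in% names(cv$best)) cfg$lr <- cv$best$lr
    write_tab(cv$table, file.path(config$out_dir, "cv_table.tsv"))
    manifest$stages$cv <- list(best = as.list(cv$best))
  }
  tr <- which(split$role == "trainval" & split$fold != 1L)
  va <- which(split$role == "trainval" & split$fold == 1L)
  model <- build_model(arch, as.list(features$widths),
                       conditions = outcomes$conditions, seed = config$seed)
  model <- suppressWarnings(
    train_fold(model, features, outcomes, tr, va, cfg))
  model$stats <- stats
  write_tab(model$log, file.path(config$out_dir, "training_log.tsv"))

  # --- score + evaluate
  scores <- predict_log_risk(model, features)
  itest <- which(split$role == "internal_test")
  etest <- which(split$role == "external_test")
  ci_internal <- vapply(seq_along(outcomes$conditions), function(d) {
    ev <- outcomes$event[itest, d]
    if (sum(ev) == 0) return(NA_real_)
    batched_cindex(scores[itest, d], outcomes$time[itest, d], ev,
                   seed = config$seed)$c_index
  }, numeric(1))
  names(ci_internal) <- outcomes$conditions
  manifest$stages$score <- list(
    mean_internal_cindex = mean(ci_internal, na.rm = TRUE),
    n_internal = length(itest), n_external = length(etest))
  write_tab(data.frame(condition = outcomes$conditions,
                       internal_cindex = ci_internal),
            file.path(config$out_dir, "cindex_internal.tsv"))

  # --- quartiles + KM stratification
  bins <- fit_quartile_bins(scores, cohort$sex, split)
  quart <- assign_quartiles(scores, cohort$sex, bins)
  km_rows <- lapply(outcomes$conditions, function(d) {
    lr <- tryCatch(logrank_test(outcomes$time[, d], outcomes$event[, d],
                                quart[, d]),
                   error = function(e) list(statistic = NA, p = NA))
    data.frame(condition = d, logrank_chisq = lr$statistic, p = lr$p)
  })
  km_tab <- do.call(rbind, km_rows)
  write_tab(km_tab, file.path(config$out_dir, "km_logrank.tsv"))
  manifest$stages$km <- list(min_logrank_p = min(km_tab$p, na.rm = TRUE))

  # --- correlation clustering
  ci_for_filter <- ifelse(is.na(ci_internal), 0, ci_internal)
  cluster <- tryCatch(
    correlation_cluster(quart, ci_for_filter, cohort$statin_user,
                        cindex_threshold = config$cindex_threshold,
                        alpha = config$alpha,
                        edge_threshold = config$edge_threshold,
                        exclude_statin = config$exclude_statin),
    error = function(e) NULL)
  if (!is.null(cluster)) {
    write_tab(as.data.frame(cluster$r), file.path(config$out_dir, "correlations.tsv"))
    write_tab(cluster$edges, file.path(config$out_dir, "graph_edges.tsv"))
    write_tab(data.frame(merge1 = cluster$tree$merge[, 1],
                         merge2 = cluster$tree$merge[, 2],
                         height = cluster$tree$height),
              file.path(config$out_dir, "linkage.tsv"))
    manifest$stages$cluster <- list(retained = length(cluster$conditions),
                                    family = cluster$family_size,
                                    threshold = cluster$threshold,
                                    n_zeroed = cluster$n_zeroed,
                                    n_edges = nrow(cluster$edges))
  }

  # --- prognostic pair models
  cin <- if (!is.null(cluster)) cluster$conditions else outcomes$conditions
  if (!is.null(config$prognostic_max_pairs)) {
    cin <- utils::head(cin, config$prognostic_max_pairs)
  }
  prog <- run_all_pairs(cohort, outcomes, quart, conditions_in = cin,
                        conditions_out = cin,
                        spec_template = list(
                          horizon_months = config$horizon_months,
                          min_uncensored = config$min_uncensored,
                          sex_restriction = config$sex_restriction),
                        alpha = config$alpha)
  pt <- prognostic_table(prog)
  if (!is.null(pt)) write_tab(pt, file.path(config$out_dir, "prognostic.tsv"))
  manifest$stages$prognostic <- as.list(prog$summary)

  # --- saliency
  sal <- list()
  for (s in sort(unique(cohort$sex))) {
    raw <- gradient_saliency(model, features, rows = which(cohort$sex == s))
    sal[[s]] <- normalize_saliency(raw)
    write_tab(as.data.frame(sal[[s]]$values),
              file.path(config$out_dir, paste0("saliency_", s, ".tsv")))
  }
  manifest$stages$saliency <- list(sexes = names(sal))

  files <- list.files(config$out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest$checksums <- as.list(tools::md5sum(files))
  names(manifest$checksums) <- basename(files)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(cohort = cohort, outcomes = outcomes, registry = registry,
                 truth = truth, split = split, model = model,
                 scores = scores, cindex_internal = ci_internal,
                 quartiles = quart, km = km_tab, cluster = cluster,
                 prognostic = prog, saliency = sal, manifest = manifest))
}
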