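#' @name cohort_files
#' @title Cohort file formats
#'
#' @description
#' Cohorts travel as a pair of delimited tables plus a condition registry
#' (delimiter auto-detected from extension: `.csv` comma, otherwise tab).
#'
#' The traits table has a two-row header: row one holds column names, row
#' two a tag per column — `id`, `sex`, `center`, `statin`, `assess_age`, a
#' trait group tag (`demog`, `bb`, `bbc`, `sbc`, `blood`), or `age` for
#' measurement-age companion columns (named `age_<trait>`). Spatial traits
#' are stored wide with systematic names `<tissue>_slice###`.
#'
#' The outcomes table starts with a `#baseline=` line (birth or assessment)
#' followed by a standard header `id`, then `time_<condition>` /
#' `event_<condition>` pairs in years from the declared baseline. The
#' registry lists `condition`, `type`, `sex_restriction`
#' (none/female/male).
NULL

delim_for <- function(path) if (grepl("\\.csv$", path)) "," else "\t"

VALID_GROUPS <- c("demog", "bb", "bbc", "sbc", "blood")

#' Write a cohort file pair
#'
#' @param cohort a `cohort`.
#' @param outcomes an `outcome_table`.
#' @param registry condition registry data frame.
#' @param traits_path,outcomes_path,registry_path output paths.
#' @return invisibly, the three paths.
#' @seealso [read_cohort()], [cohort_files]
#' @export
write_cohort <- function(cohort, outcomes, registry,
                         traits_path, outcomes_path, registry_path) {
  d <- delim_for(traits_path)
  tn <- colnames(cohort$traits)
  age_cols <- colnames(cohort$meas_age)
  hdr1 <- c("id", "sex", "center", "statin_user", "assessment_age",
            tn, paste0("age_", age_cols))
  hdr2 <- c("id", "sex", "center", "statin", "assess_age",
            unname(cohort$groups[tn]), rep("age", length(age_cols)))
  body <- cbind(cohort$ids, cohort$sex, cohort$center,
                as.integer(cohort$statin_user),
                format(cohort$assessment_age, digits = 10),
                apply(cohort$traits, 2, format, digits = 10),
                apply(cohort$meas_age, 2, format, digits = 10))
  con <- file(traits_path, "w")
  writeLines(c(paste(hdr1, collapse = d), paste(hdr2, collapse = d)), con)
  utils::write.table(body, con, sep = d, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  close(con)

  d2 <- delim_for(outcomes_path)
  ot <- data.frame(id = outcomes$ids, check.names = FALSE)
  for (cd in outcomes$conditions) {
    ot[[paste0("time_", cd)]] <- outcomes$time[, cd]
    ot[[paste0("event_", cd)]] <- outcomes$event[, cd]
  }
  con <- file(outcomes_path, "w")
  writeLines(paste0("#baseline=", outcomes$baseline), con)
  utils::write.table(ot, con, sep = d2, row.names = FALSE, quote = FALSE)
  close(con)

  utils::write.table(registry, registry_path, sep = delim_for(registry_path),
                     row.names = FALSE, quote = FALSE)
  invisible(c(traits_path, outcomes_path, registry_path))
}

#' Read a cohort file pair with ingest filtering
#'
#' Individuals with any missing covariate are dropped (full covariate
#' records are required downstream); the number of dropped rows is reported
#' with a message. Identifiers must agree between the traits and outcomes
#' tables.
#'
#' @param traits_path,outcomes_path,registry_path input paths written by
#'   [write_cohort()] or conforming to [cohort_files].
#' @return list with `cohort`, `outcomes`, `registry`, `n_dropped`.
#' @export
read_cohort <- function(traits_path, outcomes_path, registry_path) {
  d <- delim_for(traits_path)
  two <- readLines(traits_path, n = 2L)
  hdr1 <- strsplit(two[1], d, fixed = TRUE)[[1]]
  hdr2 <- strsplit(two[2], d, fixed = TRUE)[[1]]
  if (length(hdr1) != length(hdr2)) {
    stop("traits file header rows have different lengths")
  }
  known <- c("id", "sex", "center", "statin", "assess_age", "age",
             VALID_GROUPS)
  bad <- which(!(hdr2 %in% known))
  if (length(bad)) {
    stop("unknown group tag '", hdr2[bad[1]], "' for column '",
         hdr1[bad[1]], "'")
  }
  df <- utils::read.table(traits_path, sep = d, skip = 2L,
                          col.names = hdr1, check.names = FALSE,
                          stringsAsFactors = FALSE)
  colnames(df) <- hdr1

  keep <- stats::complete.cases(df)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " individual(s) dropped for missing covariates")
  }
  df <- df[keep, , drop = FALSE]

  trait_cols <- hdr1[hdr2 %in% VALID_GROUPS]
  groups <- stats::setNames(hdr2[hdr2 %in% VALID_GROUPS], trait_cols)
  age_cols <- hdr1[hdr2 == "age"]

  cohort <- structure(list(
    ids = as.character(df$id),
    sex = as.character(df$sex),
    center = as.character(df$center),
    statin_user = as.logical(as.integer(df$statin_user)),
    assessment_age = as.numeric(df$assessment_age),
    traits = local({
      m <- as.matrix(df[, trait_cols, drop = FALSE]) * 1.0
      rownames(m) <- NULL
      m
    }),
    groups = groups,
    meas_age = local({
      m <- as.matrix(df[, age_cols, drop = FALSE]) * 1.0
      dimnames(m) <- list(NULL, sub("^age_", "", age_cols))
      m
    })), class = "cohort")

  d2 <- delim_for(outcomes_path)
  first <- readLines(outcomes_path, n = 1L)
  baseline <- "birth"
  skip <- 0L
  if (startsWith(first, "#baseline=")) {
    baseline <- sub("^#baseline=", "", first)
    skip <- 1L
  }
  ot <- utils::read.table(outcomes_path, sep = d2, header = TRUE,
                          skip = skip, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ot <- ot[match(cohort$ids, as.character(ot$id)), , drop = FALSE]
  if (any(is.na(ot$id)) || !identical(as.character(ot$id), cohort$ids)) {
    stop("mismatched ids between traits and outcomes files")
  }
  tcols <- grep("^time_", colnames(ot), value = TRUE)
  cond <- sub("^time_", "", tcols)
  time <- as.matrix(ot[, paste0("time_", cond), drop = FALSE]) * 1.0
  event <- as.matrix(ot[, paste0("event_", cond), drop = FALSE]) * 1L
  dimnames(time) <- dimnames(event) <- list(NULL, cond)
  outcomes <- structure(list(ids = cohort$ids, time = time, event = event,
                             conditions = cond, baseline = baseline),
                        class = "outcome_table")

  registry <- utils::read.table(registry_path, sep = delim_for(registry_path),
                                header = TRUE, stringsAsFactors = FALSE)
  list(cohort = cohort, outcomes = outcomes, registry = registry,
       n_dropped = n_dropped)
}

#' Assign train-val / internal-test / external-test roles and CV folds
#'
#' Individuals from the designated external center(s) form the external
#' test set. The remainder is split into train-val and internal test by a
#' seeded uniform draw, and train-val is partitioned into `n_folds`
#' cross-validation folds (unstratified seeded draw).
#'
#' @param cohort a `cohort`.
#' @param external_centers character vector of external center labels.
#' @param test_fraction fraction of non-external individuals held out as
#'   internal test.
#' @param n_folds number of cross-validation folds (default 5).
#' @param seed integer seed.
#' @return object of class `split_assignment`: `role` (factor trainval /
#'   internal_test / external_test) and `fold` (integer, `NA` outside
#'   train-val).
#' @export
make_splits <- function(cohort, external_centers, test_fraction = 0.15,
                        n_folds = 5L, seed = 1L) {
  n <- length(cohort$ids)
  is_ext <- cohort$center %in% external_centers
  if (!any(is_ext)) {
    warning("no individuals in external center(s): ",
            paste(external_centers, collapse = ", "),
            "; external test set is empty")
  }
  role <- rep("trainval", n)
  role[is_ext] <- "external_test"
  rest <- which(!is_ext)
  rng <- local({
    set.seed(seed)
    list(test = sample(rest, size = round(test_fraction * length(rest))),
         u = stats::runif(n))
  })
  role[rng$test] <- "internal_test"
  role <- factor(role, levels = c("trainval", "internal_test",
                                  "external_test"))
  fold <- rep(NA_integer_, n)
  tv <- which(role == "trainval")
  set.seed(seed + 1L)
  fold[tv] <- sample(rep_len(seq_len(n_folds), length(tv)))
  structure(list(role = role, fold = fold, n_folds = as.integer(n_folds)),
            class = "split_assignment")
}

#' Fit preprocessing statistics on the train-val rows only
#'
#' Continuous variables (traits, assessment age, measurement ages) are
#' centred and scaled to zero mean and unit standard deviation using
#' statistics computed from the train-val split only (denominator n-1);
#' categorical variables (sex) record their observed level sets. Test rows
#' never contribute, which is asserted by the leakage-guard tests.
#'
#' @param cohort a `cohort`.
#' @param split a `split_assignment`.
#' @return object of class `preprocess_stats`.
#' @export
fit_preprocess <- function(cohort, split) {
  tv <- which(split$role == "trainval")
  if (!length(tv)) stop("train-val split is empty")
  num <- cbind(cohort$traits, assessment_age = cohort$assessment_age,
               `colnames<-`(cohort$meas_age,
                            paste0("age_", colnames(cohort$meas_age))))
  mu <- colMeans(num[tv, , drop = FALSE])
  sd <- apply(num[tv, , drop = FALSE], 2, stats::sd)
  zero <- which(sd <= 0 | !is.finite(sd))
  if (length(zero)) {
    stop("zero-variance continuous variable in train-val: ",
         colnames(num)[zero[1]])
  }
  structure(list(mean = mu, sd = sd,
                 categories = list(sex = sort(unique(cohort$sex[tv])))),
            class = "preprocess_stats")
}

one_hot <- function(x, levels, what) {
  unseen <- setdiff(unique(x), levels)
  if (length(unseen)) {
    stop("unseen ", what, " category at apply time: ",
         paste(unseen, collapse = ", "))
  }
  m <- outer(x, levels, `==`) * 1.0
  colnames(m) <- paste0(what, "_", levels)
  m
}

#' Build model-ready feature blocks per trait group
#'
#' Continuous variables are z-scored with the fitted train-val statistics;
#' sex is one-hot encoded into the `demog` block; each non-demographic
#' group's block is concatenated with its z-scored measurement-age
#' companion columns.
#'
#' @param cohort a `cohort`.
#' @param stats a `preprocess_stats` from [fit_preprocess()].
#' @return list with `blocks` (named list of numeric matrices, one per
#'   active trait group) and `widths` (named integer vector).
#' @export
apply_preprocess <- function(cohort, stats) {
  num <- cbind(cohort$traits, assessment_age = cohort$assessment_age,
               `colnames<-`(cohort$meas_age,
                            paste0("age_", colnames(cohort$meas_age))))
  z <- sweep(sweep(num, 2, stats$mean[colnames(num)]), 2,
             stats$sd[colnames(num)], "/")
  blocks <- list()
  for (g in intersect(VALID_GROUPS, unique(unname(cohort$groups)))) {
    cols <- names(cohort$groups)[cohort$groups == g]
    b <- z[, cols, drop = FALSE]
    if (g == "demog") {
      b <- cbind(one_hot(cohort$sex, stats$categories$sex, "sex"),
                 b, assessment_age = z[, "assessment_age"])
    } else {
      acols <- paste0("age_", cols)
      acols <- acols[acols %in% colnames(z)]
      b <- cbind(b, z[, acols, drop = FALSE])
    }
    blocks[[g]] <- b
  }
  list(blocks = blocks,
       widths = vapply(blocks, ncol, integer(1)))
}

#' @export
print.split_assignment <- function(x, ...) {
  cat("<split_assignment>", paste(sprintf("%s:%d", levels(x$role),
                                          as.integer(table(x$role))),
                                  collapse = " "),
      sprintf("(%d folds)\n", x$n_folds))
  invisible(x)
}
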