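tiny_features <- function(n = 40, seed = 1) {
  set.seed(seed)
  list(blocks = list(demog = matrix(rnorm(n * 3), n,
                                    dimnames = list(NULL, paste0("d", 1:3))),
                     blood = matrix(rnorm(n * 5), n,
                                    dimnames = list(NULL, paste0("b", 1:5)))),
       widths = c(demog = 3L, blood = 5L))
}

test_that("model wiring: concatenation width, parameter count, deterministic init", {
  ft <- tiny_features()
  arch <- arch_config(c("demog", "blood"), n_conditions = 4, k = 8,
                      encoder_hidden = 1, encoder_width = 6,
                      head_hidden = 1, head_width = 5)
  m <- build_model(arch, as.list(ft$widths), seed = 3)
  expect_equal(m$dims$head[1], 2 * 8)
  # hand-computed: enc demog 3->6->8, enc blood 5->6->8, head 16->5->4
  count <- (3 * 6 + 6) + (6 * 8 + 8) + (5 * 6 + 6) + (6 * 8 + 8) +
    (16 * 5 + 5) + (5 * 4 + 4)
  expect_equal(m$n_params, count)

  m2 <- build_model(arch, as.list(ft$widths), seed = 3)
  expect_identical(predict_log_risk(m, ft), predict_log_risk(m2, ft))
  expect_error(build_model(arch, list(demog = 3)), "blood")
})

test_that("prediction is deterministic, row-consistent, and shape-checked", {
  ft <- tiny_features()
  arch <- arch_config(c("demog", "blood"), n_conditions = 2, k = 4,
                      dropout = 0.5)
  m <- build_model(arch, as.list(ft$widths), seed = 1)
  h1 <- predict_log_risk(m, ft)
  h2 <- predict_log_risk(m, ft)
  expect_identical(h1, h2)    # dropout disabled at prediction time

  ftdup <- ft
  ftdup$blocks <- lapply(ft$blocks, function(b) rbind(b[1, ], b[1, ]))
  hd <- predict_log_risk(m, ftdup)
  expect_identical(hd[1, ], hd[2, ])

  ftbad <- ft
  ftbad$blocks$blood <- ft$blocks$blood[, 1:3]
  expect_error(predict_log_risk(m, ftbad), "width")
})

test_that("training descends on a learnable instance and aborts on divergence", {
  fx <- linear_fixture(n = 1200, n_conditions = 2, seed = 21)
  m <- train_small(fx, k = 8, epochs = 6)
  expect_lt(tail(m$log$train_loss, 1), m$log$train_loss[1])

  arch <- arch_config(names(fx$features$blocks), n_conditions = 2, k = 8)
  m0 <- build_model(arch, as.list(fx$features$widths),
                    conditions = fx$outcomes$conditions, seed = 1)
  tr <- which(fx$split$role == "trainval" & fx$split$fold != 1)
  va <- which(fx$split$role == "trainval" & fx$split$fold == 1)
  expect_error(
    suppressWarnings(train_fold(m0, fx$features, fx$outcomes, tr, va,
                                train_config(epochs = 3, lr = 1e4,
                                             batch_size = 256))),
    "diverged")
  expect_error(train_fold(m0, fx$features, fx$outcomes, 1:10, 5:20,
                          train_config()))
})

test_that("signal-free cohorts give chance-level validation concordance", {
  cis <- vapply(1:3, function(s) {
    W <- matrix(0, 2, 16)
    cfg <- generator_config(n_individuals = 1500, n_conditions = 2,
                            n_latent = 2,
                            trait_group_sizes = c(demog = 2, bb = 4, bbc = 4,
                                                  sbc = 0, blood = 6),
                            true_weights = W, cluster_strength = 0,
                            seed = 100 + s)
    sim <- generate_cohort(cfg)
    split <- make_splits(sim$cohort, "ext", seed = s)
    st <- fit_preprocess(sim$cohort, split)
    ft <- apply_preprocess(sim$cohort, st)
    arch <- arch_config(names(ft$blocks), n_conditions = 2, k = 8)
    m <- build_model(arch, as.list(ft$widths),
                     conditions = sim$outcomes$conditions, seed = s)
    tr <- which(split$role == "trainval" & split$fold != 1)
    va <- which(split$role == "trainval" & split$fold == 1)
    m <- suppressWarnings(train_fold(m, ft, sim$outcomes, tr, va,
                                     train_config(epochs = 10,
                                                  batch_size = 256,
                                                  seed = s)))
    tail(m$log$val_cindex, 1)
  }, numeric(1))
  expect_true(all(abs(cis - 0.5) < 0.05))
})

test_that("cross-validation selects sensible configurations reproducibly", {
  fx <- linear_fixture(n = 1000, n_conditions = 2, seed = 31)
  arch <- arch_config(names(fx$features$blocks), n_conditions = 2, k = 8)
  cfg <- train_config(epochs = 6, batch_size = 256, seed = 1)

  single <- cross_validate(fx$features, fx$outcomes, fx$split,
                           data.frame(lr = 2e-3), arch, cfg, folds = 1:2)
  expect_equal(single$best$lr, 2e-3)

  grid <- data.frame(lr = c(0, 2e-3))
  cv1 <- cross_validate(fx$features, fx$outcomes, fx$split, grid, arch, cfg,
                        folds = 1:2)
  expect_equal(cv1$best$lr, 2e-3)   # a frozen model can never win
  cv2 <- cross_validate(fx$features, fx$outcomes, fx$split, grid, arch, cfg,
                        folds = 1:2)
  expect_identical(cv1$table$val_cindex, cv2$table$val_cindex)
  expect_error(cross_validate(fx$features, fx$outcomes, fx$split,
                              data.frame(), arch, cfg), "empty")
})

test_that("quartile bins reproduce the textbook small cases", {
  scores <- matrix(1:8, 8, 1, dimnames = list(NULL, "c1"))
  sex <- rep("female", 8)
  split <- list(role = factor(rep("trainval", 8),
                              levels = c("trainval", "internal_test",
                                         "external_test")),
                fold = rep(1L, 8), n_folds = 1L)
  class(split) <- "split_assignment"
  bins <- fit_quartile_bins(scores, sex, split)
  q <- assign_quartiles(scores, sex, bins)
  expect_equal(unname(q[, 1]), rep(1:4, each = 2))

  # degenerate distribution: left-closed convention sends everyone to bin 1
  sc2 <- matrix(rep(3.3, 8), 8, 1, dimnames = list(NULL, "c1"))
  b2 <- fit_quartile_bins(sc2, sex, split)
  expect_warning(q2 <- assign_quartiles(sc2, sex, b2), "degenerate")
  expect_true(all(q2 == 1L))

  sc3 <- matrix(1:4, 4, 1, dimnames = list(NULL, "c1"))
  split3 <- split; split3$role <- split3$role[1:4]; split3$fold <- rep(1L, 4)
  bn <- binarize_scores(sc3, rep("female", 4), split3)
  expect_equal(unname(bn[, 1]), c(1L, 1L, 2L, 2L))
  # a score equal to the median falls below it
  scm <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "c1"))
  splitm <- split; splitm$role <- splitm$role[1:3]; splitm$fold <- rep(1L, 3)
  expect_equal(unname(binarize_scores(scm, rep("f", 3), splitm)[, 1]),
               c(1L, 1L, 2L))
})

test_that("train-val quartile occupancy is balanced to one individual", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(40:200, 1)
    scores <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "c1"))
    sex <- sample(c("f", "m"), n, replace = TRUE)
    split <- structure(list(role = factor(rep("trainval", n),
                                          levels = c("trainval",
                                                     "internal_test",
                                                     "external_test")),
                            fold = rep(1L, n), n_folds = 1L),
                       class = "split_assignment")
    bins <- fit_quartile_bins(scores, sex, split)
    q <- assign_quartiles(scores, sex, bins)
    for (s in unique(sex)) {
      counts <- tabulate(q[sex == s, 1], 4)
      expect_lte(max(counts) - min(counts), 2)
      expect_lte(max(abs(counts - sum(sex == s) / 4)), 1 + 1e-9)
    }
  }
})

test_that("bins and binarization never leak information from test rows", {
  fx <- linear_fixture(n = 600, n_conditions = 2, seed = 41)
  set.seed(1)
  scores <- matrix(rnorm(600 * 2), 600, 2,
                   dimnames = list(NULL, fx$outcomes$conditions))
  sex <- fx$cohort$sex
  bins <- fit_quartile_bins(scores, sex, fx$split)
  scores2 <- scores
  test_rows <- fx$split$role != "trainval"
  scores2[test_rows, ] <- scores2[test_rows, ] + 1000
  bins2 <- fit_quartile_bins(scores2, sex, fx$split)
  expect_identical(bins, bins2)

  # binarized assignment agrees with the quartile halves on train-val
  q <- assign_quartiles(scores, sex, bins)
  bn <- binarize_scores(scores, sex, fx$split)
  tv <- which(!test_rows)
  expect_identical(unname(bn[tv, ] > 1), unname(q[tv, ] > 2))
})

test_that("a trained model approaches the generating-process oracle", {
  fx <- linear_fixture(n = 3000, n_conditions = 2, seed = 51)
  m <- train_small(fx, k = 16, epochs = 40)
  h <- predict_log_risk(m, fx$features)
  va <- which(fx$split$role == "trainval" & fx$split$fold == 1)
  for (d in 1:2) {
    oracle <- batched_cindex(fx$truth$eta[va, d], fx$outcomes$time[va, d],
                             fx$outcomes$event[va, d], seed = 1)$c_index
    got <- batched_cindex(h[va, d], fx$outcomes$time[va, d],
                          fx$outcomes$event[va, d], seed = 1)$c_index
    expect_gt(got, oracle - 0.05)
    expect_gt(cor(h[, d], fx$truth$eta[, d], method = "spearman"), 0.7)
  }
})
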