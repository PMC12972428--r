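# Independent brute-force oracles, deliberately naive: they enumerate the
# definitions directly and share no code with the package internals.

# negative Breslow partial log-likelihood by explicit risk-set enumeration
brute_cox_neg_loglik <- function(h, time, event) {
  s <- 0
  for (i in which(event == 1)) {
    rs <- which(time >= time[i])
    s <- s + h[i] - log(sum(exp(h[rs])))
  }
  -s / sum(event == 1)
}

# Harrell's C by O(n^2) pair enumeration
brute_cindex <- function(h, time, event) {
  conc <- tied <- comp <- 0
  n <- length(h)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      comparable <- (event[i] == 1 && time[i] < time[j]) ||
        (event[i] == 1 && event[j] == 0 && time[i] == time[j])
      if (!comparable) next
      comp <- comp + 1
      if (h[i] > h[j]) conc <- conc + 1
      else if (h[i] == h[j]) tied <- tied + 1
    }
  }
  list(c_index = (conc + 0.5 * tied) / comp, comparable = comp)
}

# naive average-linkage agglomeration on a distance matrix: returns the
# sequence of merge heights
brute_upgma_heights <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- c()
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        dd <- mean(d[clusters[[a]], clusters[[b]]])
        if (dd < bestd) { bestd <- dd; best <- c(a, b) }
      }
    }
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# small linear synthetic cohort used across model tests
linear_fixture <- function(n = 5000, n_conditions = 3, seed = 11,
                           cluster_strength = 0.3) {
  W <- matrix(0, n_conditions, 16)
  picks <- list(c(7, 8, 9), c(3, 10, 11), c(4, 12, 13))
  vals <- list(c(0.8, -0.6, 0.5), c(0.7, 0.6, -0.5), c(0.6, 0.6, 0.6))
  for (d in seq_len(n_conditions)) {
    i <- 1 + (d - 1) %% 3
    W[d, picks[[i]]] <- vals[[i]]
  }
  cfg <- generator_config(n_individuals = n, n_conditions = n_conditions,
                          n_latent = 2,
                          trait_group_sizes = c(demog = 2, bb = 4, bbc = 4,
                                                sbc = 0, blood = 6),
                          true_weights = W,
                          cluster_strength = cluster_strength, seed = seed)
  sim <- generate_cohort(cfg)
  split <- make_splits(sim$cohort, "ext", seed = seed)
  stats <- fit_preprocess(sim$cohort, split)
  features <- apply_preprocess(sim$cohort, stats)
  c(sim, list(split = split, stats = stats, features = features, W = W))
}

train_small <- function(fx, k = 16, epochs = 40, lr = 2e-3, seed = 1) {
  arch <- arch_config(names(fx$features$blocks),
                      n_conditions = ncol(fx$truth$eta), k = k)
  model <- build_model(arch, as.list(fx$features$widths),
                       conditions = fx$outcomes$conditions, seed = seed)
  tr <- which(fx$split$role == "trainval" & fx$split$fold != 1)
  va <- which(fx$split$role == "trainval" & fx$split$fold == 1)
  suppressWarnings(train_fold(model, fx$features, fx$outcomes, tr, va,
                              train_config(epochs = epochs, lr = lr,
                                           batch_size = 512, seed = seed)))
}
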