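#' Architecture configuration for the multi-encoder risk network
#'
#' The network has one encoder per active trait group, each mapping its
#' feature block to a fixed-length feature vector of length `k`; the
#' encoder outputs are concatenated and passed to a shared predictor head
#' with one scalar log-risk output per condition. Encoders and head are
#' fully connected with ReLU activations; depth and width are
#' configurable.
#'
#' @param groups character vector of active trait groups.
#' @param n_conditions number of condition outputs.
#' @param k encoder feature length; conventional choices are 128, 256 or
#'   512, but any positive integer is accepted (small values suit small
#'   synthetic cohorts).
#' @param encoder_hidden number of hidden layers per encoder (default 1).
#' @param encoder_width hidden width per encoder; default
#'   `max(k, input width)`.
#' @param head_hidden number of hidden layers in the shared head.
#' @param head_width hidden width of the head; default `k`.
#' @param dropout dropout rate on hidden activations during training.
#' @param activation `"relu"` (default) or `"identity"`; the latter makes
#'   the whole network linear, useful as an analytic reference.
#' @return object of class `arch_config`.
#' @export
arch_config <- function(groups, n_conditions, k = 128L,
                        encoder_hidden = 1L, encoder_width = NULL,
                        head_hidden = 1L, head_width = NULL,
                        dropout = 0, activation = c("relu", "identity")) {
  stopifnot(length(groups) >= 1, n_conditions >= 1, k >= 1,
            dropout >= 0, dropout < 1)
  structure(list(groups = groups, n_conditions = as.integer(n_conditions),
                 k = as.integer(k),
                 encoder_hidden = as.integer(encoder_hidden),
                 encoder_width = encoder_width,
                 head_hidden = as.integer(head_hidden),
                 head_width = head_width,
                 dropout = dropout,
                 activation = match.arg(activation)),
            class = "arch_config")
}

#' Training configuration
#'
#' @param lr learning rate of the adaptive (Adam) optimizer.
#' @param lam weight decay coefficient; applied as the explicit
#'   \eqn{\lambda\lVert\theta\rVert^2} penalty in the objective, so its
#'   gradient enters the optimizer like any other loss term.
#' @param epochs maximum training epochs.
#' @param batch_size mini-batch size; the partial likelihood is computed
#'   within mini-batches, a standard approximation to the full-cohort
#'   likelihood.
#' @param patience early-stopping patience on the validation objective.
#' @param cindex_batch batch size for the validation concordance index.
#' @param seed RNG seed for shuffling, initialization and dropout.
#' @param verbose print per-epoch progress.
#' @return object of class `train_config`.
#' @export
train_config <- function(lr = 1e-3, lam = 1e-5, epochs = 30L,
                         batch_size = 512L, patience = 8L,
                         cindex_batch = 2048L, seed = 1L,
                         verbose = FALSE) {
  stopifnot(lr >= 0, lam >= 0, epochs >= 1, batch_size >= 2, patience >= 1)
  structure(list(lr = lr, lam = lam, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 cindex_batch = as.integer(cindex_batch),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

relu <- function(x) (x > 0) * x

layer_dims <- function(arch, widths) {
  enc <- list()
  for (g in arch$groups) {
    w_in <- widths[[g]]
    hid <- rep(if (is.null(arch$encoder_width)) max(arch$k, w_in)
               else arch$encoder_width, arch$encoder_hidden)
    enc[[g]] <- c(w_in, hid, arch$k)
  }
  hw <- if (is.null(arch$head_width)) arch$k else arch$head_width
  head <- c(length(arch$groups) * arch$k, rep(hw, arch$head_hidden),
            arch$n_conditions)
  list(encoders = enc, head = head)
}

#' Build an untrained multi-encoder risk model
#'
#' He-initialized weights under a fixed seed; identical seeds give
#' identical initial parameters and therefore identical initial outputs.
#'
#' @param arch an `arch_config`.
#' @param widths named widths of the feature blocks (from
#'   [apply_preprocess()]); must cover every active group.
#' @param conditions condition names for the outputs.
#' @param seed initialization seed.
#' @return object of class `risk_model` with a reported `n_params`.
#' @export
build_model <- function(arch, widths, conditions = NULL, seed = 1L) {
  missing <- setdiff(arch$groups, names(widths))
  if (length(missing)) {
    stop("no feature block width for group(s): ",
         paste(missing, collapse = ", "))
  }
  dims <- layer_dims(arch, widths)
  set.seed(seed)
  par <- list()
  mk <- function(d_in, d_out) {
    list(W = matrix(stats::rnorm(d_in * d_out, sd = sqrt(2 / d_in)),
                    d_in, d_out),
         b = rep(0, d_out))
  }
  for (g in arch$groups) {
    dd <- dims$encoders[[g]]
    for (l in seq_len(length(dd) - 1L)) {
      lay <- mk(dd[l], dd[l + 1L])
      par[[sprintf("enc.%s.%d.W", g, l)]] <- lay$W
      par[[sprintf("enc.%s.%d.b", g, l)]] <- lay$b
    }
  }
  dh <- dims$head
  for (l in seq_len(length(dh) - 1L)) {
    lay <- mk(dh[l], dh[l + 1L])
    par[[sprintf("head.%d.W", l)]] <- lay$W
    par[[sprintf("head.%d.b", l)]] <- lay$b
  }
  if (is.null(conditions)) conditions <- paste0("cond_", seq_len(arch$n_conditions))
  structure(list(par = par, arch = arch, dims = dims,
                 conditions = conditions,
                 widths = unlist(widths[arch$groups]),
                 n_params = sum(vapply(par, length, numeric(1))),
                 stats = NULL, log = NULL),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> groups [%s] k=%d -> %d conditions, %d parameters%s\n",
              paste(x$arch$groups, collapse = ","), x$arch$k,
              x$arch$n_conditions, x$n_params,
              if (is.null(x$log)) " (untrained)" else ""))
  invisible(x)
}

# forward pass; when train=TRUE, inverted dropout masks are drawn from the
# current RNG stream and cached for the backward pass
forward_model <- function(model, blocks, train = FALSE) {
  arch <- model$arch
  p <- model$par
  act <- if (identical(arch$activation, "identity")) identity else relu
  drop <- if (train) arch$dropout else 0
  cache <- list(enc = list(), drop = drop)
  feats <- list()
  for (g in arch$groups) {
    A <- blocks[[g]]
    nl <- length(model$dims$encoders[[g]]) - 1L
    lays <- vector("list", nl)
    for (l in seq_len(nl)) {
      Z <- A %*% p[[sprintf("enc.%s.%d.W", g, l)]]
      Z <- sweep(Z, 2, p[[sprintf("enc.%s.%d.b", g, l)]], "+")
      Anew <- act(Z)
      M <- NULL
      if (drop > 0) {
        M <- matrix(stats::rbinom(length(Anew), 1, 1 - drop),
                    nrow(Anew)) / (1 - drop)
        Anew <- Anew * M
      }
      lays[[l]] <- list(A_in = A, Z = Z, M = M)
      A <- Anew
    }
    cache$enc[[g]] <- lays
    feats[[g]] <- A
  }
  C <- do.call(cbind, feats)
  A <- C
  nh <- length(model$dims$head) - 1L
  hl <- vector("list", nh)
  for (l in seq_len(nh)) {
    Z <- A %*% p[[sprintf("head.%d.W", l)]]
    Z <- sweep(Z, 2, p[[sprintf("head.%d.b", l)]], "+")
    if (l < nh) {
      Anew <- act(Z)
      M <- NULL
      if (drop > 0) {
        M <- matrix(stats::rbinom(length(Anew), 1, 1 - drop),
                    nrow(Anew)) / (1 - drop)
        Anew <- Anew * M
      }
      hl[[l]] <- list(A_in = A, Z = Z, M = M)
      A <- Anew
    } else {
      hl[[l]] <- list(A_in = A, Z = Z, M = NULL)
      A <- Z
    }
  }
  cache$head <- hl
  list(h = A, cache = cache)
}

# backward pass: gradients of sum(dH * h) w.r.t. parameters and inputs
backward_model <- function(model, cache, dH) {
  arch <- model$arch
  p <- model$par
  lin <- identical(arch$activation, "identity")
  grads <- list()
  nh <- length(model$dims$head) - 1L
  dA <- dH
  for (l in rev(seq_len(nh))) {
    lay <- cache$head[[l]]
    dZ <- if (l < nh) {
      d <- if (lin) dA else dA * (lay$Z > 0)
      if (!is.null(lay$M)) d <- d * lay$M
      d
    } else dA
    grads[[sprintf("head.%d.W", l)]] <- crossprod(lay$A_in, dZ)
    grads[[sprintf("head.%d.b", l)]] <- colSums(dZ)
    dA <- dZ %*% t(p[[sprintf("head.%d.W", l)]])
  }
  # split concatenated feature gradient back into groups
  dX <- list()
  off <- 0L
  for (g in arch$groups) {
    dAg <- dA[, (off + 1L):(off + arch$k), drop = FALSE]
    off <- off + arch$k
    nl <- length(model$dims$encoders[[g]]) - 1L
    for (l in rev(seq_len(nl))) {
      lay <- cache$enc[[g]][[l]]
      d <- dAg
      if (!is.null(lay$M)) d <- d * lay$M
      dZ <- if (lin) d else d * (lay$Z > 0)
      grads[[sprintf("enc.%s.%d.W", g, l)]] <- crossprod(lay$A_in, dZ)
      grads[[sprintf("enc.%s.%d.b", g, l)]] <- colSums(dZ)
      dAg <- dZ %*% t(p[[sprintf("enc.%s.%d.W", g, l)]])
    }
    dX[[g]] <- dAg
  }
  list(grads = grads, dX = dX)
}

weight_norm_sq <- function(par) sum(vapply(par, function(w) sum(w^2),
                                           numeric(1)))

subset_blocks <- function(blocks, idx) {
  lapply(blocks, function(b) b[idx, , drop = FALSE])
}

#' Predict per-condition log-risk scores
#'
#' Deterministic forward pass with dropout disabled.
#'
#' @param model a trained `risk_model`.
#' @param features feature blocks from [apply_preprocess()] using the
#'   model's own preprocessing statistics.
#' @return numeric matrix, individuals x conditions.
#' @export
predict_log_risk <- function(model, features) {
  blocks <- features$blocks
  missing <- setdiff(model$arch$groups, names(blocks))
  if (length(missing)) stop("missing feature block(s): ",
                            paste(missing, collapse = ", "))
  for (g in model$arch$groups) {
    if (ncol(blocks[[g]]) != model$dims$encoders[[g]][1]) {
      stop("feature block '", g, "' has width ", ncol(blocks[[g]]),
           ", model expects ", model$dims$encoders[[g]][1])
    }
  }
  h <- forward_model(model, blocks, train = FALSE)$h
  colnames(h) <- model$conditions
  h
}

mean_val_cindex <- function(h, outcome, idx, batch, seed) {
  cs <- c()
  for (d in seq_len(ncol(h))) {
    ev <- outcome$event[idx, d]
    if (sum(ev) == 0) next
    cs <- c(cs, batched_cindex(h[idx, d], outcome$time[idx, d], ev,
                               batch_size = batch, seed = seed)$c_index)
  }
  mean(cs)
}

#' Train the risk network on one fold
#'
#' Minimizes the multi-condition Cox objective by mini-batch gradient
#' descent with the Adam update rule. The partial likelihood and its
#' gradient are evaluated within each mini-batch; the weight-decay
#' penalty \eqn{\lambda\lVert\theta\rVert^2} contributes
#' \eqn{2\lambda\theta} to every gradient. The validation objective and
#' the mean validation batched concordance index are logged per epoch,
#' the best-epoch parameters (lowest validation objective) are retained,
#' and training stops early when the validation objective has not
#' improved for `patience` epochs. A non-finite training loss aborts
#' with diagnostics.
#'
#' @param model an untrained or trained `risk_model`.
#' @param features feature blocks from [apply_preprocess()].
#' @param outcome an `outcome_table` with birth baseline.
#' @param train_idx,val_idx disjoint row indices.
#' @param cfg a `train_config`.
#' @return the trained `risk_model`; `$log` holds per-epoch metrics.
#' @export
train_fold <- function(model, features, outcome, train_idx, val_idx, cfg) {
  stopifnot(inherits(cfg, "train_config"),
            length(intersect(train_idx, val_idx)) == 0)
  blocks <- features$blocks
  D <- model$arch$n_conditions
  par <- model$par
  mstate <- lapply(par, function(w) w * 0)
  vstate <- lapply(par, function(w) w * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  set.seed(cfg$seed)
  best <- list(obj = Inf, par = par, epoch = 0L)
  logs <- list()
  eventless_warned <- FALSE
  for (epoch in seq_len(cfg$epochs)) {
    idx <- sample(train_idx)
    starts <- seq(1L, length(idx), by = cfg$batch_size)
    ep_loss <- 0; nb <- 0L
    for (s in starts) {
      bidx <- idx[s:min(s + cfg$batch_size - 1L, length(idx))]
      if (length(bidx) < 2L) next
      mod_tmp <- model; mod_tmp$par <- par
      fw <- forward_model(mod_tmp, subset_blocks(blocks, bidx),
                          train = TRUE)
      h <- fw$h
      dH <- matrix(0, nrow(h), D)
      gsum <- 0; K <- 0L
      for (d in seq_len(D)) {
        ev <- outcome$event[bidx, d]
        if (sum(ev) == 0) next
        tt <- outcome$time[bidx, d]
        gsum <- gsum + cox_partial_loglik_neg(h[, d], tt, ev)
        dH[, d] <- cox_grad_h(h[, d], tt, ev)
        K <- K + 1L
      }
      if (K == 0L) {
        if (!eventless_warned) {
          warning("mini-batch with no events in any condition skipped")
          eventless_warned <- TRUE
        }
        next
      }
      dH <- dH / K
      loss <- gsum / K + cfg$lam * weight_norm_sq(par)
      if (!is.finite(loss)) {
        stop(sprintf("training diverged at epoch %d (loss=%g, lr=%g)",
                     epoch, loss, cfg$lr))
      }
      ep_loss <- ep_loss + loss; nb <- nb + 1L
      bw <- backward_model(mod_tmp, fw$cache, dH)
      step <- step + 1L
      for (nm in names(par)) {
        g <- bw$grads[[nm]] + 2 * cfg$lam * par[[nm]]
        mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * g
        vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * g^2
        mhat <- mstate[[nm]] / (1 - b1^step)
        vhat <- vstate[[nm]] / (1 - b2^step)
        par[[nm]] <- par[[nm]] - cfg$lr * mhat / (sqrt(vhat) + eps)
      }
    }
    mod_tmp <- model; mod_tmp$par <- par
    hv <- forward_model(mod_tmp, subset_blocks(blocks, val_idx))$h
    val_obj <- suppressWarnings(
      multi_disease_objective(hv, list(time = outcome$time[val_idx, , drop = FALSE],
                                       event = outcome$event[val_idx, , drop = FALSE]),
                              weight_norm_sq(par), cfg$lam)$l)
    val_ci <- mean_val_cindex(forward_model(mod_tmp, blocks)$h, outcome,
                              val_idx, cfg$cindex_batch, cfg$seed)
    logs[[epoch]] <- data.frame(epoch = epoch,
                                train_loss = ep_loss / max(nb, 1L),
                                val_obj = val_obj, val_cindex = val_ci)
    if (cfg$verbose) {
      message(sprintf("epoch %d train %.4f val %.4f val-C %.4f", epoch,
                      ep_loss / max(nb, 1L), val_obj, val_ci))
    }
    if (is.finite(val_obj) && val_obj < best$obj) {
      best <- list(obj = val_obj, par = par, epoch = epoch)
    } else if (epoch - best$epoch >= cfg$patience) break
  }
  model$par <- best$par
  model$log <- do.call(rbind, logs)
  model$best_epoch <- best$epoch
  model
}

#' Cross-validated hyperparameter selection
#'
#' Trains one model per grid point and fold, scores each by the mean
#' validation-fold concordance index (fold mean of the per-fold
#' condition-mean batched C-index), and returns the argmax
#' configuration together with the full selection table. Both the
#' fold-then-condition mean and the pooled condition mean are logged.
#'
#' @param features feature blocks from [apply_preprocess()].
#' @param outcome an `outcome_table`.
#' @param split a `split_assignment` with fold labels.
#' @param grid data frame of hyperparameter combinations; recognized
#'   columns: `k`, `lam`, `lr`, `dropout` (missing columns fall back to
#'   the templates).
#' @param arch_template an `arch_config` providing fixed settings.
#' @param cfg_template a `train_config` providing fixed settings.
#' @param folds which folds to use (default all).
#' @return list with `best` (row of `grid`), `best_index`, `table`
#'   (per grid point x fold metrics), and `model_factory` notes.
#' @export
cross_validate <- function(features, outcome, split, grid,
                           arch_template, cfg_template,
                           folds = NULL) {
  if (is.null(grid) || nrow(grid) == 0) stop("empty hyperparameter grid")
  if (is.null(folds)) folds <- seq_len(split$n_folds)
  if (length(folds) < 2) stop("cross-validation needs at least two folds")
  rows <- list()
  for (gi in seq_len(nrow(grid))) {
    arch <- arch_template
    cfg <- cfg_template
    if ("k" %in% names(grid)) arch$k <- as.integer(grid$k[gi])
    if ("dropout" %in% names(grid)) arch$dropout <- grid$dropout[gi]
    if ("lam" %in% names(grid)) cfg$lam <- grid$lam[gi]
    if ("lr" %in% names(grid)) cfg$lr <- grid$lr[gi]
    for (f in folds) {
      tr <- which(split$role == "trainval" & split$fold != f)
      va <- which(split$role == "trainval" & split$fold == f)
      model <- build_model(arch, as.list(vapply(features$blocks, ncol,
                                                integer(1))),
                           conditions = outcome$conditions,
                           seed = cfg$seed + f)
      model <- suppressWarnings(
        train_fold(model, features, outcome, tr, va, cfg))
      h <- predict_log_risk(model, features)
      ci <- mean_val_cindex(h, outcome, va, cfg$cindex_batch, cfg$seed)
      rows[[length(rows) + 1L]] <- cbind(grid[gi, , drop = FALSE],
                                         data.frame(fold = f,
                                                    val_cindex = ci))
    }
  }
  tab <- do.call(rbind, rows)
  agg <- stats::aggregate(val_cindex ~ grid_row,
                          data = cbind(tab, grid_row = rep(seq_len(nrow(grid)),
                                                           each = length(folds))),
                          FUN = mean)
  best_i <- agg$grid_row[which.max(agg$val_cindex)]
  list(best = grid[best_i, , drop = FALSE], best_index = best_i,
       table = tab, fold_means = agg)
}
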