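#' Gradient saliency of inputs with respect to each condition output
#'
#' For every condition output d and network input variable v, the mean
#' over selected individuals of the absolute partial derivative
#' \eqn{|\partial h^d / \partial x_v|}, computed in evaluation mode
#' (dropout off) against the standardized inputs the network actually
#' receives. One-hot categorical indicators are differentiated like any
#' other input column. Sex-specific maps restrict the averaging
#' population; the model is not refitted.
#'
#' @param model a trained `risk_model`.
#' @param features feature blocks from [apply_preprocess()].
#' @param rows optional subset of individuals to average over (e.g. one
#'   sex).
#' @return nonnegative matrix, conditions x input variables, with
#'   variable names prefixed by their trait group.
#' @export
gradient_saliency <- function(model, features, rows = NULL) {
  blocks <- features$blocks[model$arch$groups]
  if (!is.null(rows)) blocks <- subset_blocks(blocks, rows)
  n <- nrow(blocks[[1]])
  D <- model$arch$n_conditions
  fw <- forward_model(model, blocks, train = FALSE)
  vnames <- unlist(lapply(names(blocks), function(g) {
    paste0(g, ".", colnames(blocks[[g]]))
  }), use.names = FALSE)
  out <- matrix(0, D, length(vnames),
                dimnames = list(model$conditions, vnames))
  for (d in seq_len(D)) {
    dH <- matrix(0, n, D)
    dH[, d] <- 1
    dX <- backward_model(model, fw$cache, dH)$dX
    out[d, ] <- unlist(lapply(names(blocks), function(g) {
      colMeans(abs(dX[[g]]))
    }), use.names = FALSE)
  }
  out
}

#' Normalize a raw saliency map within variable scopes
#'
#' Univariate traits and multivariate spatial profiles live on different
#' footings, so they are normalized separately: within each (condition,
#' scope) the importances are divided by the scope maximum
#' (`method = "max"`, default, bounding values by 1) or by the scope sum
#' (`method = "sum"`). An all-zero scope is left as zeros with a warning.
#' Normalization is monotone, so top-k rankings are preserved.
#'
#' @param raw conditions x variables matrix from [gradient_saliency()].
#' @param spatial_vars character vector (or logical mask) of the columns
#'   forming the spatial scope; the rest form the univariate scope.
#' @param method `"max"` (default) or `"sum"`.
#' @param top_k number of top univariate labels recorded per condition.
#' @return object of class `saliency_map`: `values` (normalized matrix),
#'   `scope` per variable, `top` (per-condition top-k univariate
#'   labels), `method`.
#' @export
normalize_saliency <- function(raw, spatial_vars = NULL,
                               method = c("max", "sum"), top_k = 5L) {
  method <- match.arg(method)
  if (is.null(spatial_vars)) {
    spatial <- grepl("^sbc\\.", colnames(raw))
  } else if (is.logical(spatial_vars)) {
    spatial <- spatial_vars
  } else {
    spatial <- colnames(raw) %in% spatial_vars
  }
  scope <- ifelse(spatial, "spatial", "univariate")
  vals <- raw
  for (sc in unique(scope)) {
    cols <- which(scope == sc)
    for (d in seq_len(nrow(raw))) {
      den <- if (method == "max") max(raw[d, cols]) else sum(raw[d, cols])
      if (den == 0) {
        warning("all-zero ", sc, " saliency scope for condition ",
                rownames(raw)[d], "; left as zeros")
      } else {
        vals[d, cols] <- raw[d, cols] / den
      }
    }
  }
  uni <- which(scope == "univariate")
  top <- lapply(seq_len(nrow(raw)), function(d) {
    o <- order(raw[d, uni], decreasing = TRUE)
    colnames(raw)[uni][o][seq_len(min(top_k, length(uni)))]
  })
  names(top) <- rownames(raw)
  structure(list(values = vals, scope = scope, top = top, method = method),
            class = "saliency_map")
}

#' Average a saliency map over conditions
#'
#' Arithmetic mean over conditions per variable. By default this averages
#' the normalized per-condition maps (average-of-normalized); averaging
#' raw values and then normalizing is a different summary and can be
#' obtained by passing the raw matrix.
#'
#' @param map a `saliency_map` (its normalized values are averaged) or a
#'   plain conditions x variables matrix.
#' @return named numeric vector, one summary value per variable.
#' @export
average_over_conditions <- function(map) {
  m <- if (inherits(map, "saliency_map")) map$values else map
  colMeans(m)
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("<saliency_map> %d conditions x %d variables (%d spatial), %s-normalized\n",
              nrow(x$values), ncol(x$values), sum(x$scope == "spatial"),
              x$method))
  invisible(x)
}
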