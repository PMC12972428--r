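#' Retain conditions by internal-test concordance
#'
#' Keeps conditions whose internal-test C-index is at or above the
#' threshold (inclusive).
#'
#' @param cindex named numeric vector of per-condition C-index values.
#' @param threshold retention threshold (default 0.6).
#' @return character vector of retained condition names.
#' @export
filter_conditions <- function(cindex, threshold = 0.6) {
  stopifnot(all(is.finite(cindex)))
  keep <- names(cindex)[cindex >= threshold]
  if (!length(keep)) warning("no conditions reach C-index >= ", threshold)
  keep
}

#' Pairwise Pearson correlation of risk quartiles
#'
#' Pearson's r between the integer quartile vectors of every condition
#' pair over shared individuals, with two-tailed p-values from the
#' t-distribution transform \eqn{t = r\sqrt{(n-2)/(1-r^2)}}. Statin
#' users can be excluded, mirroring the primary analysis; a permutation
#' p-value scheme is available as an alternative.
#'
#' @param quartiles integer matrix individuals x conditions.
#' @param statin_user logical per-individual statin flag.
#' @param exclude_statin drop statin users before correlating.
#' @param conditions optional subset of conditions.
#' @param p_method `"t"` (default) or `"permutation"`.
#' @param n_perm permutations when `p_method = "permutation"`.
#' @param seed permutation seed.
#' @return list with symmetric `r` and `p` matrices (`r` diagonal 1,
#'   `p` diagonal 0) and `n` individuals used. Zero-variance quartile
#'   vectors give `NA` entries with a warning.
#' @export
quartile_correlations <- function(quartiles, statin_user = NULL,
                                  exclude_statin = FALSE,
                                  conditions = NULL,
                                  p_method = c("t", "permutation"),
                                  n_perm = 1000L, seed = 1L) {
  p_method <- match.arg(p_method)
  if (!is.null(conditions)) quartiles <- quartiles[, conditions, drop = FALSE]
  if (exclude_statin) {
    if (is.null(statin_user)) stop("statin_user required to exclude statin users")
    quartiles <- quartiles[!statin_user, , drop = FALSE]
  }
  n <- nrow(quartiles)
  if (n < 3) stop("need at least 3 individuals after exclusion")
  D <- ncol(quartiles)
  sds <- apply(quartiles, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance quartile vector(s): ",
            paste(colnames(quartiles)[sds == 0], collapse = ", "),
            "; correlations recorded as missing")
  }
  r <- suppressWarnings(stats::cor(quartiles))
  diag(r) <- ifelse(sds > 0, 1, NA_real_)
  if (p_method == "t") {
    rc <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
    tstat <- rc * sqrt((n - 2) / (1 - rc^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  } else {
    set.seed(seed)
    p <- matrix(0, D, D, dimnames = dimnames(r))
    cnt <- matrix(0, D, D)
    for (b in seq_len(n_perm)) {
      qs <- apply(quartiles, 2, sample)
      cnt <- cnt + (abs(suppressWarnings(stats::cor(qs))) >= abs(r))
    }
    p <- (cnt + 1) / (n_perm + 1)
  }
  diag(p) <- 0
  p[is.na(r)] <- NA_real_
  list(r = r, p = p, n = n)
}

#' Per-test Bonferroni threshold
#'
#' @param alpha family-wise error level (default 0.05).
#' @param m number of tests in the family.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  stopifnot(m >= 1)
  alpha / m
}

#' Zero out non-significant correlations
#'
#' Entries with p above the threshold are set to zero before cosine
#' clustering; the diagonal (p = 0) is retained.
#'
#' @param r correlation matrix.
#' @param p matching p-value matrix.
#' @param threshold per-test significance threshold.
#' @return list with `r` (masked matrix) and `n_zeroed`.
#' @export
zero_nonsignificant <- function(r, p, threshold) {
  stopifnot(all(dim(r) == dim(p)))
  mask <- !is.na(p) & p > threshold
  r[mask] <- 0
  list(r = r, n_zeroed = sum(mask))
}

cosine_dist <- function(m) {
  nr <- sqrt(rowSums(m^2))
  zero <- which(nr == 0)
  if (length(zero)) {
    stop("all-zero correlation row(s), cosine distance undefined: ",
         paste(rownames(m)[zero], collapse = ", "))
  }
  s <- (m %*% t(m)) / outer(nr, nr)
  d <- 1 - s
  d[d < 0] <- 0
  d
}

#' UPGMA clustering on cosine distance between correlation rows
#'
#' Pairwise cosine distance between the rows of the (masked) correlation
#' matrix, clustered by unweighted pair group method with arithmetic mean
#' (average linkage agglomeration via [stats::hclust()]). Ties are broken
#' deterministically by lowest index pair.
#'
#' @param masked_r correlation matrix, typically from
#'   [zero_nonsignificant()].
#' @return object of class `hclust`.
#' @export
upgma_cosine <- function(masked_r) {
  if (nrow(masked_r) < 2) stop("need at least two conditions to cluster")
  d <- cosine_dist(masked_r)
  stats::hclust(stats::as.dist(d), method = "average")
}

#' Export the strong-correlation graph
#'
#' Undirected edges (a, b, r) for a < b where the masked correlation is at
#' or above the edge threshold; edge width scales with r.
#'
#' @param masked_r masked correlation matrix.
#' @param edge_threshold minimum correlation for an edge (default 0.3).
#' @return data frame with columns `a`, `b`, `r`, `width`.
#' @export
export_graph <- function(masked_r, edge_threshold = 0.3) {
  nm <- rownames(masked_r)
  if (is.null(nm)) nm <- paste0("cond_", seq_len(nrow(masked_r)))
  idx <- which(upper.tri(masked_r) & masked_r >= edge_threshold,
               arr.ind = TRUE)
  rr <- masked_r[cbind(idx[, 1], idx[, 2])]
  data.frame(a = nm[idx[, 1]], b = nm[idx[, 2]], r = rr, width = rr,
             stringsAsFactors = FALSE)[order(idx[, 1], idx[, 2]), ]
}

#' Full inter-condition correlation-clustering analysis
#'
#' Chains the primary analysis: condition retention by C-index, quartile
#' correlations (statin users excluded), Bonferroni masking over the full
#' matrix family (retained^2 entries, diagonal included), UPGMA/cosine
#' clustering, and graph export.
#'
#' @param quartiles integer quartile matrix.
#' @param cindex named per-condition internal-test C-index.
#' @param statin_user logical statin flags.
#' @param cindex_threshold retention threshold (default 0.6).
#' @param alpha family-wise level (default 0.05).
#' @param edge_threshold graph edge threshold (default 0.3).
#' @param exclude_statin exclude statin users (default TRUE).
#' @return object of class `correlation_cluster_result`.
#' @export
correlation_cluster <- function(quartiles, cindex, statin_user = NULL,
                                cindex_threshold = 0.6, alpha = 0.05,
                                edge_threshold = 0.3,
                                exclude_statin = TRUE) {
  retained <- filter_conditions(cindex, cindex_threshold)
  qc <- quartile_correlations(quartiles, statin_user,
                              exclude_statin = exclude_statin,
                              conditions = retained)
  m <- length(retained)^2
  thr <- bonferroni_threshold(alpha, m)
  masked <- zero_nonsignificant(qc$r, qc$p, thr)
  tree <- upgma_cosine(masked$r)
  edges <- export_graph(masked$r, edge_threshold)
  structure(list(conditions = retained, r = qc$r, p = qc$p,
                 family_size = m, threshold = thr,
                 masked_r = masked$r, n_zeroed = masked$n_zeroed,
                 tree = tree, edges = edges, n = qc$n),
            class = "correlation_cluster_result")
}

#' @export
print.correlation_cluster_result <- function(x, ...) {
  cat(sprintf(paste0("<correlation_cluster_result> %d conditions, family ",
                     "%d, per-test p <= %.3g, %d entries zeroed, %d edges\n"),
              length(x$conditions), x$family_size, x$threshold,
              x$n_zeroed, nrow(x$edges)))
  invisible(x)
}
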