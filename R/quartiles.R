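#' Fit sex- and condition-specific quartile bins on the train-val split
#'
#' For each (sex, condition) cell, the three quartile cut points of the
#' train-val score distribution are recorded. Test rows never contribute.
#'
#' @param scores individuals x conditions log-risk matrix.
#' @param sex per-individual sex labels.
#' @param split a `split_assignment`.
#' @return object of class `quartile_bins`: nested list
#'   `bins[[sex]][[condition]]` of nondecreasing cut points.
#' @export
fit_quartile_bins <- function(scores, sex, split) {
  tv <- split$role == "trainval"
  bins <- list()
  for (s in sort(unique(sex))) {
    bins[[s]] <- list()
    for (d in colnames(scores)) {
      x <- scores[tv & sex == s, d]
      if (!length(x)) stop("empty (sex, condition) cell: ", s, ", ", d)
      bins[[s]][[d]] <- unname(stats::quantile(x, c(0.25, 0.5, 0.75),
                                               type = 7))
    }
  }
  structure(list(bins = bins, n_cuts = 3L), class = "quartile_bins")
}

cut_scores <- function(x, cuts) {
  # left-closed bins, ties to the lower bin: a score equal to a cut stays
  # below it
  q <- rep(1L, length(x))
  for (cc in cuts) q <- q + (x > cc)
  q
}

#' Assign risk quartiles from fitted bins
#'
#' Left-closed binning with ties to the lower bin: within train-val each
#' (sex, condition) cell is balanced to 25\% per quartile up to one
#' individual; test rows may be unbalanced. A degenerate score
#' distribution (all cut points equal) maps every individual to the first
#' bin, with a warning.
#'
#' @param scores individuals x conditions log-risk matrix.
#' @param sex per-individual sex labels.
#' @param bins a `quartile_bins` from [fit_quartile_bins()].
#' @return integer matrix of quartiles in 1..4 (or 1..2 for median bins).
#' @export
assign_quartiles <- function(scores, sex, bins) {
  q <- matrix(NA_integer_, nrow(scores), ncol(scores),
              dimnames = dimnames(scores))
  warned <- FALSE
  for (s in unique(sex)) {
    if (is.null(bins$bins[[s]])) stop("no bins fitted for sex: ", s)
    rows <- which(sex == s)
    for (d in colnames(scores)) {
      cuts <- bins$bins[[s]][[d]]
      if (!warned && length(unique(cuts)) == 1L &&
          all(scores[rows, d] == cuts[1])) {
        warning("degenerate score distribution for (", s, ", ", d,
                "): all individuals assigned to bin 1")
        warned <- TRUE
      }
      q[rows, d] <- cut_scores(scores[rows, d], cuts)
    }
  }
  q
}

#' Binarize scores at the train-val median
#'
#' Two-bin variant of the quartile assignment (above vs below the sex- and
#' condition-specific train-val median); a score equal to the median falls
#' below (left-closed convention). Equals the quartile split q in \{1,2\}
#' vs q in \{3,4\} when the quartile cuts are strict.
#'
#' @inheritParams fit_quartile_bins
#' @return integer matrix with 1 = below/at median, 2 = above median.
#' @export
binarize_scores <- function(scores, sex, split) {
  tv <- split$role == "trainval"
  q <- matrix(NA_integer_, nrow(scores), ncol(scores),
              dimnames = dimnames(scores))
  for (s in sort(unique(sex))) {
    rows <- which(sex == s)
    for (d in colnames(scores)) {
      x <- scores[tv & sex == s, d]
      if (!length(x)) stop("empty (sex, condition) cell: ", s, ", ", d)
      med <- stats::median(x)
      q[rows, d] <- 1L + (scores[rows, d] > med)
    }
  }
  q
}
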