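#' Pointwise correlation of every feature with pharmacological action
#'
#' Pearson correlation between each binary feature column and the binary
#' label (positive class = antagonist, so r > 0 means
#' antagonist-associated). For two binary variables this is exactly the phi
#' coefficient of the 2x2 contingency table. Features with zero variance get
#' `NA` (marked undefined, never a fabricated zero).
#'
#' @param matrix a labelled `aifp_matrix` with at least 2 samples per class.
#' @return object of class `aifp_corr_report`: data.frame `feature_key`,
#'   `r`, `n_present`, `direction` (agonist / antagonist / undefined).
#' @export
pointwise_correlation <- function(matrix) {
  lab <- droplevels(matrix$label)
  if (!all(levels(lab) %in% c("agonist", "antagonist"))) {
    stop("matrix must contain only labelled (agonist/antagonist) samples")
  }
  y <- as.integer(matrix$label == "antagonist")
  if (sum(y) < 2 || sum(1 - y) < 2) {
    stop("need at least 2 samples per class")
  }
  r <- suppressWarnings(as.vector(cor(matrix$values, y)))
  report <- data.frame(
    feature_key = colnames(matrix$values),
    r = r,
    n_present = unname(colSums(matrix$values)),
    direction = ifelse(is.na(r), "undefined",
                       ifelse(r > 0, "antagonist", "agonist")),
    stringsAsFactors = FALSE
  )
  structure(report, class = c("aifp_corr_report", "data.frame"))
}

#' Correlation-score threshold classifier
#'
#' Scores a pose as the sum of the training correlations r over the features
#' present in it, and predicts antagonist when the score reaches a cutoff.
#' The cutoff is chosen on the training data only, by scanning a grid
#' (default: all midpoints between adjacent sorted unique training scores,
#' plus sentinels below and above) and taking the cutoff that maximises the
#' training Matthews correlation coefficient; ties break toward the smaller
#' cutoff. Features with undefined r are excluded from scoring.
#'
#' @param matrix training `aifp_matrix`.
#' @param report [pointwise_correlation()] report computed on the same
#'   training matrix.
#' @param cutoff_grid optional numeric vector of cutoffs to scan.
#' @return object of class `aifp_threshold_classifier`: feature weights,
#'   cutoff, training MCC and accuracy; `degenerate = TRUE` flags an
#'   all-scores-identical fit.
#' @export
fit_threshold_classifier <- function(matrix, report, cutoff_grid = NULL) {
  w <- report$r
  names(w) <- report$feature_key
  w <- w[!is.na(w)]
  common <- intersect(colnames(matrix$values), names(w))
  scores <- as.vector(matrix$values[, common, drop = FALSE] %*% w[common])
  y <- matrix$label == "antagonist"
  uniq <- sort(unique(scores))
  degenerate <- length(uniq) == 1
  if (is.null(cutoff_grid)) {
    cutoff_grid <- if (degenerate) uniq else {
      c(uniq[1] - 1, (uniq[-1] + uniq[-length(uniq)]) / 2,
        uniq[length(uniq)] + 1)
    }
  }
  evals <- vapply(cutoff_grid, function(cut) {
    pred <- scores >= cut
    c(mcc = mcc(sum(pred & y), sum(!pred & !y), sum(pred & !y), sum(!pred & y)),
      acc = mean(pred == y))
  }, numeric(2))
  best <- which.max(evals["mcc", ])  # which.max takes the first (smallest cutoff)
  structure(
    list(weights = w, cutoff = cutoff_grid[best],
         train_mcc = unname(evals["mcc", best]),
         train_accuracy = unname(evals["acc", best]),
         degenerate = degenerate, positive = "antagonist"),
    class = "aifp_threshold_classifier"
  )
}

#' @export
print.aifp_threshold_classifier <- function(x, ...) {
  cat(sprintf(
    "<aifp_threshold_classifier> %d weighted features, cutoff %.4f, training MCC %.3f (accuracy %.3f)%s\n",
    length(x$weights), x$cutoff, x$train_mcc, x$train_accuracy,
    if (x$degenerate) " [degenerate: constant scores]" else ""))
  invisible(x)
}

#' @export
predict.aifp_threshold_classifier <- function(object, matrix, ...) {
  common <- intersect(colnames(matrix$values), names(object$weights))
  scores <- as.vector(matrix$values[, common, drop = FALSE] %*%
                        object$weights[common])
  factor(ifelse(scores >= object$cutoff, "antagonist", "agonist"),
         levels = c("agonist", "antagonist"))
}

#' Rank interaction features by correlation strength
#'
#' @param report an [pointwise_correlation()] report.
#' @param top_k number of features to return.
#' @return data.frame sorted by |r| descending, annotated with direction and
#'   the parsed residue / receptor-atom / ligand-element / type components.
#' @export
rank_features <- function(report, top_k = 10) {
  defined <- report[!is.na(report$r), , drop = FALSE]
  ord <- order(-abs(defined$r), defined$feature_key)
  top <- defined[ord, , drop = FALSE][seq_len(min(top_k, nrow(defined))), ,
                                      drop = FALSE]
  if (nrow(top) == 0) {
    return(cbind(top, data.frame(residue_number = integer(0),
                                 receptor_atom = character(0),
                                 ligand_element = character(0),
                                 type = character(0))))
  }
  out <- cbind(top, parse_feature_key(top$feature_key))
  rownames(out) <- NULL
  out
}

#' Write a correlation report as CSV
#' @param report an `aifp_corr_report`.
#' @param path output file.
#' @export
write_corr_report <- function(report, path) {
  write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
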