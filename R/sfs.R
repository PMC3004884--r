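# criterion used by the greedy search: training accuracy of a Fisher LDA
# refit on the candidate column set, classified by nearest latent mean
.sfs_criterion <- function(X, y) {
  core <- .lda_core(X, y)
  if (is.null(core)) return(-Inf)
  Z <- X %*% core$W
  mean(.nearest_mean(Z, core$means2d, core$classes) == y)
}

#' Sequential forward feature selection
#'
#' Greedy wrapper selection for the discriminant classifier: at each step
#' the candidate column that maximises the selection criterion (training
#' accuracy of a Fisher LDA refit on the candidate set; ties go to the
#' lower column index) is added. Candidates are validated with a
#' correlation-based criterion: a column whose absolute Pearson
#' correlation with any already-selected column exceeds
#' `correlation_threshold` is skipped, so near-duplicate spectral points
#' are not selected twice. Selection stops at `max_features`, when no
#' admissible candidate remains, or when no candidate improves the
#' criterion.
#'
#' @param x n x p feature matrix.
#' @param labels class label per row; at least 2 classes.
#' @param max_features cap on the number of selected features
#'   (default 13, the classical classifier size).
#' @param correlation_threshold absolute Pearson correlation above which
#'   a candidate is inadmissible (default 0.8).
#' @return list of class `feature_selection`: `features` (selected column
#'   indices in selection order), `criterion` (trace of the criterion
#'   value after each addition).
#' @export
sequential_forward_select <- function(x, labels, max_features = 13L,
                                      correlation_threshold = 0.8) {
  X <- as.matrix(x)
  y <- as.character(labels)
  if (length(unique(y)) < 2L)
    .mrsdx_stop("need at least 2 classes", "mrsdx_invalid_argument")
  if (max_features < 1L)
    .mrsdx_stop("max_features must be >= 1", "mrsdx_invalid_argument")
  p <- ncol(X)
  col_sd <- apply(X, 2L, sd)

  selected <- integer()
  trace <- numeric()
  best <- -Inf
  repeat {
    cand <- setdiff(seq_len(p), selected)
    if (length(selected)) {
      ok <- col_sd[cand] > 0
      if (any(ok)) {
        r <- abs(cor(X[, cand[ok], drop = FALSE], X[, selected, drop = FALSE]))
        r[is.na(r)] <- 0
        ok[ok] <- apply(r, 1L, max) <= correlation_threshold
      }
      cand <- cand[ok]
    }
    if (length(cand) == 0L) {
      if (length(selected) == 0L)
        .mrsdx_stop("no admissible candidate feature at step 1",
                    "mrsdx_selection_error")
      break
    }
    crits <- vapply(cand, function(j)
      .sfs_criterion(X[, c(selected, j), drop = FALSE], y), numeric(1))
    ibest <- which.max(crits)      # first max -> lowest column index wins ties
    if (crits[ibest] <= best && length(selected) > 0L) break
    selected <- c(selected, cand[ibest])
    best <- crits[ibest]
    trace <- c(trace, best)
    if (length(selected) >= max_features) break
  }
  structure(list(features = selected, criterion = trace),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("<feature_selection> %d features: %s\n", length(x$features),
              paste(x$features, collapse = ", ")))
  invisible(x)
}
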