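#' Default classifier trainer: forward selection then Fisher LDA
#'
#' The standard training route bundled for [bootstrap_evaluate()]:
#' sequential forward selection capped at `max_features`, then a Fisher
#' LDA fit on the selected columns.
#'
#' @param max_features selection cap passed to
#'   [sequential_forward_select()].
#' @param correlation_threshold correlation admissibility threshold.
#' @return a function `(x, labels) -> fisher_lda` model.
#' @export
lda_trainer <- function(max_features = 13L, correlation_threshold = 0.8) {
  force(max_features); force(correlation_threshold)
  function(x, labels) {
    sel <- sequential_forward_select(x, labels, max_features,
                                     correlation_threshold)
    fisher_lda_fit(x, labels, features = sel$features)
  }
}

#' Bootstrap out-of-bag evaluation of a classifier
#'
#' Draws `B` bootstrap resamples stratified by class (sampling with
#' replacement within each class, so no class can vanish from a
#' resample), refits the full training procedure — including feature
#' selection — on each resample, and measures accuracy on the out-of-bag
#' rows. A resample whose out-of-bag set is empty is redrawn (counted in
#' `redraws`). Fully reproducible for a given seed.
#'
#' @param x n x p feature matrix.
#' @param labels class label per row.
#' @param trainer function `(x, labels) -> model` where the model
#'   supports `predict(model, x)`; default [lda_trainer()].
#' @param B number of bootstrap replicates (default 200).
#' @param seed integer seed; mandatory for reproducibility.
#' @return list of class `evaluation_result`: `accuracy` (mean OOB
#'   accuracy), `ci` (2.5/97.5 percentile interval), `oob_accuracies`,
#'   aggregated OOB `confusion`, `B`, `redraws`, `n`.
#' @export
bootstrap_evaluate <- function(x, labels, trainer = lda_trainer(),
                               B = 200L, seed) {
  X <- as.matrix(x)
  y <- as.character(labels)
  if (B < 1L) .mrsdx_stop("B must be >= 1", "mrsdx_invalid_argument")
  if (missing(seed)) .mrsdx_stop("seed is mandatory", "mrsdx_invalid_argument")
  set.seed(as.integer(seed))

  by_class <- split(seq_along(y), y)
  lev <- unique(y)
  confusion <- table(truth = factor(character(), lev),
                     predicted = factor(character(), lev))
  acc <- numeric(B)
  redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- unlist(lapply(by_class, function(rows)
        rows[sample.int(length(rows), length(rows), replace = TRUE)]),
        use.names = FALSE)
      oob <- setdiff(seq_along(y), idx)
      if (length(oob) > 0L) break
      redraws <- redraws + 1L
    }
    model <- trainer(X[idx, , drop = FALSE], y[idx])
    pred <- predict(model, X[oob, , drop = FALSE])
    acc[b] <- mean(pred == y[oob])
    confusion <- confusion + table(truth = factor(y[oob], lev),
                                   predicted = factor(pred, lev))
  }
  structure(
    list(accuracy = mean(acc),
         ci = quantile(acc, c(0.025, 0.975), names = FALSE),
         oob_accuracies = acc, confusion = confusion,
         B = as.integer(B), redraws = redraws, n = nrow(X)),
    class = "evaluation_result"
  )
}
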