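# Fast internal core shared by fisher_lda_fit and the SFS criterion.
# X: n x d numeric matrix (already column-subset), y: factor-like labels.
# Returns list(W 2-col projection, means2d, classes, evals) or NULL on failure.
.lda_core <- function(X, y, shrinkage = 1e-6) {
  classes <- unique(y)
  g <- length(classes)
  d <- ncol(X)
  n <- nrow(X)
  mu <- colMeans(X)
  Sw <- matrix(0, d, d)
  Sb <- matrix(0, d, d)
  for (cl in classes) {
    rows <- which(y == cl)
    Xc <- X[rows, , drop = FALSE]
    mc <- colMeans(Xc)
    Xc <- sweep(Xc, 2L, mc)
    Sw <- Sw + crossprod(Xc)
    dm <- mc - mu
    Sb <- Sb + length(rows) * tcrossprod(dm)
  }
  tr <- sum(diag(Sw))
  if (tr <= 0) tr <- 1
  SwR <- Sw + diag(shrinkage * tr / d, d)

  M <- tryCatch(solve(SwR, Sb), error = function(e) NULL)
  if (is.null(M)) return(NULL)
  eg <- eigen(M)
  ev <- Re(eg$values)
  ord <- order(ev, decreasing = TRUE)
  keep <- ord[seq_len(min(2L, d))]
  W <- Re(eg$vectors[, keep, drop = FALSE])
  if (ncol(W) == 1L) W <- cbind(W, 0)  # degenerate 1-feature case: y axis 0

  Z <- X %*% W
  means2d <- t(vapply(classes, function(cl)
    colMeans(Z[y == cl, , drop = FALSE]), numeric(2)))
  rownames(means2d) <- as.character(classes)
  list(W = W, means2d = means2d, classes = as.character(classes),
       evals = ev[ord[seq_len(min(2L, d))]], Sw = Sw, Sb = Sb)
}

# nearest-2D-mean predictions for a projected matrix Z (ties -> first class)
.nearest_mean <- function(Z, means2d, classes) {
  d2 <- outer(Z[, 1], means2d[, 1], `-`)^2 + outer(Z[, 2], means2d[, 2], `-`)^2
  classes[max.col(-d2, ties.method = "first")]
}

#' Fit a Fisher linear discriminant model
#'
#' Solves the generalized eigenproblem of the between-class versus
#' within-class scatter matrices and keeps the two leading discriminant
#' directions, which define the 2D latent display space. The within-class
#' scatter is regularised with a small trace-scaled ridge
#' (`shrinkage * tr(Sw)/d * I`) so slices with more features than samples
#' remain solvable. With two classes only the first axis carries
#' discriminative information; the second is the zero-eigenvalue
#' complement, kept for plotting. Classification is by the nearest class
#' mean in the latent plane, which with equal priors and shared isotropic
#' latent covariance coincides with the Fisher rule and makes the decision
#' boundaries an exactly computable planar partition
#' (see [decision_boundaries()]).
#'
#' @param x n x p numeric matrix of feature vectors (one case per row).
#' @param labels class label per row; at least 2 classes.
#' @param features optional column indices to use (e.g. from
#'   [sequential_forward_select()]); default all columns.
#' @param shrinkage ridge fraction for the within-class scatter.
#' @param normalisation `"unit"` or `"none"`; recorded so that
#'   [project()] can apply the same treatment to new cases. The rows of
#'   `x` are assumed already normalised accordingly.
#' @return object of class `fisher_lda`: feature indices, projection
#'   matrix (`p_selected` x 2), 2D class means, class names (in order of
#'   first appearance; ties in prediction resolve to the earlier class),
#'   eigenvalues and scatter matrices.
#' @export
fisher_lda_fit <- function(x, labels, features = NULL, shrinkage = 1e-6,
                           normalisation = "none") {
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (nrow(x) != length(labels))
    .mrsdx_stop("labels length must match rows of x", "mrsdx_invalid_argument")
  if (length(unique(labels)) < 2L)
    .mrsdx_stop("need at least 2 classes", "mrsdx_invalid_argument")
  if (is.null(features)) features <- seq_len(ncol(x))
  Xs <- x[, features, drop = FALSE]
  core <- .lda_core(Xs, labels, shrinkage)
  if (is.null(core)) {
    bad <- which(apply(Xs, 2L, sd) == 0)
    .mrsdx_stop(sprintf(
      "within-class scatter singular even after shrinkage%s",
      if (length(bad)) sprintf(" (degenerate feature column %d)", features[bad[1]])
      else ""), "mrsdx_fit_error")
  }
  structure(
    list(features = as.integer(features), projection = core$W,
         means2d = core$means2d, classes = core$classes,
         eigenvalues = core$evals, Sw = core$Sw, Sb = core$Sb,
         normalisation = normalisation),
    class = "fisher_lda"
  )
}

#' @export
print.fisher_lda <- function(x, ...) {
  cat(sprintf("<fisher_lda> %d features, classes: %s\n",
              length(x$features), paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Project feature vectors into the 2D discriminant space
#'
#' @param model a [fisher_lda_fit()] model.
#' @param x numeric vector of full feature length, or a matrix with one
#'   case per row. The model's feature subset and stored normalisation
#'   are applied.
#' @return for a single vector, `c(x, y)`; for a matrix, an n x 2 matrix.
#' @export
project <- function(model, x) {
  stopifnot(inherits(model, "fisher_lda"))
  single <- is.null(dim(x))
  X <- if (single) matrix(as.numeric(x), nrow = 1L) else as.matrix(x)
  if (ncol(X) < max(model$features))
    .mrsdx_stop(sprintf("feature vector length %d incompatible with model (needs >= %d)",
                        ncol(X), max(model$features)), "mrsdx_invalid_argument")
  if (identical(model$normalisation, "unit")) {
    nrm <- sqrt(rowSums(X^2))
    if (any(nrm == 0))
      .mrsdx_stop("cannot unit-normalise a zero vector", "mrsdx_invalid_argument")
    X <- X / nrm
  }
  Z <- X[, model$features, drop = FALSE] %*% model$projection
  colnames(Z) <- c("x", "y")
  if (single) Z[1L, ] else Z
}

#' Predict class labels with a fitted discriminant model
#'
#' Assigns each case to the class whose 2D latent mean is nearest in
#' Euclidean distance; ties resolve to the class declared first in the
#' model.
#'
#' @param object a [fisher_lda_fit()] model.
#' @param newdata feature vector or matrix (one case per row).
#' @param ... unused.
#' @return character vector of class labels.
#' @export
predict.fisher_lda <- function(object, newdata, ...) {
  Z <- project(object, newdata)
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1L)
  .nearest_mean(Z, object$means2d, object$classes)
}

#' Explicit decision boundaries in the latent plane
#'
#' Under nearest-latent-mean classification the true boundaries between
#' classes are the perpendicular bisectors of the 2D class means. Returns
#' each pairwise bisector as a line equation `a*x + b*y = c` (only pairs
#' whose bisector actually borders both regions are flagged active) and
#' the class regions as convex polygons: the intersection of the
#' half-planes nearer to that class, clipped to a plot rectangle.
#'
#' @param model a [fisher_lda_fit()] model.
#' @param region plot rectangle `c(xmin, xmax, ymin, ymax)`; default the
#'   bounding box of the class means padded by 3 times its largest side.
#' @return list of class `lda_boundaries` with `lines` (data.frame:
#'   `class_a`, `class_b`, `a`, `b`, `c`) and `regions` (named list of
#'   polygon vertex matrices).
#' @export
decision_boundaries <- function(model, region = NULL) {
  stopifnot(inherits(model, "fisher_lda"))
  M <- model$means2d
  cls <- model$classes
  if (is.null(region)) {
    span <- max(max(M[, 1]) - min(M[, 1]), max(M[, 2]) - min(M[, 2]), 1)
    region <- c(min(M[, 1]) - 3 * span, max(M[, 1]) + 3 * span,
                min(M[, 2]) - 3 * span, max(M[, 2]) + 3 * span)
  }
  pairs <- utils::combn(length(cls), 2L)
  lines <- data.frame(class_a = character(), class_b = character(),
                      a = numeric(), b = numeric(), c = numeric())
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    ab <- M[i2, ] - M[i1, ]
    cc <- (sum(M[i2, ]^2) - sum(M[i1, ]^2)) / 2
    lines <- rbind(lines, data.frame(class_a = cls[i1], class_b = cls[i2],
                                     a = ab[1], b = ab[2], c = cc))
  }

  rect <- matrix(c(region[1], region[3],
                   region[2], region[3],
                   region[2], region[4],
                   region[1], region[4]), ncol = 2, byrow = TRUE)
  regions <- lapply(seq_along(cls), function(i) {
    poly <- rect
    for (k in seq_along(cls)) {
      if (k == i || nrow(poly) == 0L) next
      # half-plane of points nearer mean i than mean k
      nvec <- M[k, ] - M[i, ]
      cc <- (sum(M[k, ]^2) - sum(M[i, ]^2)) / 2
      poly <- .clip_halfplane(poly, nvec, cc)
    }
    poly
  })
  names(regions) <- cls
  structure(list(lines = lines, regions = regions, region = region,
                 classes = cls),
            class = "lda_boundaries")
}

# Sutherland-Hodgman clip of polygon (vertex matrix, counterclockwise)
# against half-plane {p : n.p <= c}
.clip_halfplane <- function(poly, nvec, cval) {
  if (nrow(poly) == 0L) return(poly)
  out <- matrix(numeric(), ncol = 2L)
  np <- nrow(poly)
  f <- poly %*% nvec - cval
  for (i in seq_len(np)) {
    j <- if (i == np) 1L else i + 1L
    pi_in <- f[i] <= 1e-12
    pj_in <- f[j] <= 1e-12
    if (pi_in) out <- rbind(out, poly[i, ])
    if (pi_in != pj_in) {
      t <- f[i] / (f[i] - f[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

# even-odd (ray casting) point-in-polygon; boundary points are ambiguous
.point_in_polygon <- function(pt, poly) {
  n <- nrow(poly)
  if (n < 3L) return(FALSE)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > pt[2]) != (yj > pt[2]) &&
        pt[1] < (xj - xi) * (pt[2] - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

#' Assign latent points to boundary regions
#'
#' Region lookup by point-in-polygon test against the polygons of
#' [decision_boundaries()] — an independent geometric route to the same
#' partition that [predict.fisher_lda()] computes by nearest mean.
#'
#' @param boundaries an `lda_boundaries` object.
#' @param z 2-column matrix of latent points.
#' @return character vector of class labels (`NA` for points outside the
#'   clipped plot region).
#' @export
assign_region <- function(boundaries, z) {
  stopifnot(inherits(boundaries, "lda_boundaries"))
  z <- if (is.null(dim(z))) matrix(z, nrow = 1L) else as.matrix(z)
  vapply(seq_len(nrow(z)), function(i) {
    for (cl in boundaries$classes) {
      if (.point_in_polygon(z[i, ], boundaries$regions[[cl]])) return(cl)
    }
    NA_character_
  }, character(1))
}

#' Evaluate a fitted model on a held-out test set
#'
#' Projects and classifies held-out cases without refitting; reports
#' accuracy and the per-class confusion matrix.
#'
#' @param model a [fisher_lda_fit()] model.
#' @param x test feature matrix (one case per row).
#' @param labels true labels.
#' @return list of class `evaluation_result` with `accuracy`,
#'   `confusion`, `n`.
#' @export
evaluate_on_test <- function(model, x, labels) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (nrow(x) == 0L)
    .mrsdx_stop("empty test set", "mrsdx_invalid_argument")
  if (nrow(x) != length(labels))
    .mrsdx_stop("labels length must match rows of x", "mrsdx_invalid_argument")
  pred <- predict(model, x)
  lev <- union(model$classes, unique(labels))
  confusion <- table(truth = factor(labels, lev), predicted = factor(pred, lev))
  structure(
    list(accuracy = mean(pred == labels), confusion = confusion,
         n = nrow(x), B = NULL, oob_accuracies = NULL),
    class = "evaluation_result"
  )
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> accuracy %.3f on %d cases", x$accuracy, x$n))
  if (!is.null(x$B)) cat(sprintf(" (bootstrap B=%d, OOB mean)", x$B))
  cat("\n")
  invisible(x)
}
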