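test_that("range restriction retains exactly the grid points in 0.01-4.05 ppm", {
  ax <- ppm_axis()
  expected <- sum(ax >= 0.01 & ax <= 4.05)   # brute-force count
  s <- canonical_spectrum(rnorm(512))
  v <- restrict_range(s)
  expect_length(v, expected)
  expect_true(all(attr(v, "ppm") >= 0.01 & attr(v, "ppm") <= 4.05))
  # every dropped neighbour of the slice is outside the band
  idx <- attr(v, "index")
  expect_true(ax[min(idx) - 1] > 4.05)
  expect_true(ax[max(idx) + 1] < 0.01)
  # values are the contiguous slice
  expect_equal(as.numeric(v), s$intensities[idx])
  expect_equal(as.numeric(restrict_range(canonical_spectrum(rep(0, 512)))),
               rep(0, expected))
})

test_that("TE concatenation keeps short first with aligned column bookkeeping", {
  a <- canonical_spectrum(rnorm(512), te_class = "short")
  b <- canonical_spectrum(rnorm(512), te_class = "long")
  v <- concat_te(a, b)
  single <- length(restrict_range(a))
  expect_length(v, 2L * single)
  expect_equal(v[1:single], as.numeric(restrict_range(a)))
  expect_equal(v[(single + 1):(2 * single)], as.numeric(restrict_range(b)))
  pp <- attr(v, "ppm")
  expect_equal(pp[1:single], pp[(single + 1):(2 * single)])
  expect_error(concat_te(b, a), class = "mrsdx_invalid_argument")
})

test_that("feature normalisation is scale invariant", {
  v <- rnorm(50)
  u <- normalize_features(v)
  expect_equal(sqrt(sum(u^2)), 1, tolerance = 1e-12)
  expect_equal(normalize_features(3.7 * v), u)
  expect_identical(normalize_features(v, "none"), v)
  expect_error(normalize_features(rep(0, 5)), class = "mrsdx_invalid_argument")
})

test_that("sequential forward selection picks the informative column and skips duplicates", {
  set.seed(21)
  n <- 40
  labels <- rep(c("a", "b"), each = n / 2)
  x <- matrix(rnorm(n * 6), n, 6)
  x[labels == "b", 4] <- x[labels == "b", 4] + 8   # only column 4 separates
  sel <- sequential_forward_select(x, labels, max_features = 3)
  expect_identical(sel$features[1], 4L)
  # verify by exhaustive single-column training accuracy
  single_acc <- vapply(1:6, function(j) {
    m <- fisher_lda_fit(x, labels, features = j)
    mean(predict(m, x) == labels)
  }, numeric(1))
  expect_identical(which.max(single_acc), 4L)

  # a duplicated informative column is blocked by the correlation rule
  xdup <- cbind(x, x[, 4])
  sel2 <- sequential_forward_select(xdup, labels, max_features = 5)
  expect_false(7L %in% sel2$features)

  # cap respected on a wider problem
  set.seed(22)
  xw <- matrix(rnorm(60 * 40), 60, 40)
  yw <- rep(c("a", "b", "c"), each = 20)
  xw[yw == "b", 1] <- xw[yw == "b", 1] + 2
  xw[yw == "c", 2] <- xw[yw == "c", 2] + 2
  sel3 <- sequential_forward_select(xw, yw, max_features = 13)
  expect_lte(length(sel3$features), 13L)
  expect_identical(anyDuplicated(sel3$features), 0L)
})

test_that("Fisher LDA matches brute-force generalized-eigen directions", {
  set.seed(23)
  for (trial in 1:5) {
    g <- sample(2:3, 1)
    p <- sample(3:10, 1)
    n <- sample((g * 3):30, 1)
    labels <- sample(letters[1:g], n, replace = TRUE)
    while (length(unique(labels)) < g) labels <- sample(letters[1:g], n, replace = TRUE)
    x <- matrix(rnorm(n * p), n, p) +
      outer(as.integer(factor(labels)), seq_len(p) / p)
    model <- fisher_lda_fit(x, labels)
    W_oracle <- oracle_lda_directions(x, labels)
    z1 <- x %*% model$projection[, 1]
    z1o <- x %*% W_oracle[, 1]
    expect_lt(abs(abs(cor(z1, z1o)) - 1), 1e-8)
    if (g == 3) {
      z2 <- x %*% model$projection[, 2]
      z2o <- x %*% W_oracle[, 2]
      expect_lt(abs(abs(cor(z2, z2o)) - 1), 1e-6)
    }
  }
})

test_that("LDA first axis follows the mean difference for isotropic classes", {
  set.seed(24)
  n <- 100
  x <- rbind(matrix(rnorm(n * 4), n, 4),
             matrix(rnorm(n * 4), n, 4) + matrix(c(5, 2, -3, 1), n, 4, byrow = TRUE))
  labels <- rep(c("a", "b"), each = n)
  model <- fisher_lda_fit(x, labels)
  w <- model$projection[, 1]
  dm <- c(5, 2, -3, 1)
  cosine <- abs(sum(w * dm)) / sqrt(sum(w^2) * sum(dm^2))
  expect_gt(cosine, 0.99)

  # MASS cross-check of the discriminant direction
  fit <- MASS::lda(x, grouping = labels)
  expect_lt(abs(abs(cor(x %*% w, x %*% fit$scaling[, 1])) - 1), 1e-6)
})

test_that("collinear class means give a rank-1 between-scatter", {
  set.seed(25)
  base <- matrix(rnorm(60 * 3, 0, 0.1), 60, 3)
  shift <- rep(c(0, 1, 2), each = 20)           # means on a line
  x <- base + outer(shift, c(1, 1, 1))
  model <- fisher_lda_fit(x, rep(c("a", "b", "c"), each = 20))
  expect_gt(model$eigenvalues[1], 100 * abs(model$eigenvalues[2]))
})

test_that("projection is linear and prediction is nearest-mean with declared-order ties", {
  toy <- toy_gaussians()
  model <- fisher_lda_fit(toy$x, toy$labels)
  v <- toy$x[1, ]; w <- toy$x[25, ]
  expect_equal(project(model, 2 * v + 3 * w),
               2 * project(model, v) + 3 * project(model, w),
               tolerance = 1e-10)

  # class-mean input projects onto the stored class mean
  xa <- toy$x[toy$labels == "a", ]
  expect_equal(unname(project(model, colMeans(xa))),
               unname(model$means2d["a", ]), tolerance = 1e-10)

  # midpoint of two latent means -> first-declared class
  mid2d <- (model$means2d[1, ] + model$means2d[2, ]) / 2
  pseudo <- model
  d2 <- colSums((t(pseudo$means2d) - mid2d)^2)
  expect_identical(
    mrsdx:::.nearest_mean(matrix(mid2d, 1), model$means2d, model$classes),
    model$classes[which.min(d2)])

  expect_error(project(model, rnorm(2)), class = "mrsdx_invalid_argument")

  # well-separated classes classify accurately
  big <- toy_gaussians(n_per_class = 100L, seed = 26)
  m2 <- fisher_lda_fit(big$x, big$labels)
  expect_gte(mean(predict(m2, big$x) == big$labels), 0.95)
})

test_that("decision boundaries are equidistant bisectors partitioning the plane", {
  toy <- toy_gaussians(n_per_class = 15L, seed = 27)
  model <- fisher_lda_fit(toy$x, toy$labels)
  bd <- decision_boundaries(model)

  # two-class case: single bisector, equidistant at sampled points
  two <- toy_gaussians(n_per_class = 12L, seed = 28, classes = c("a", "b"))
  m2 <- fisher_lda_fit(two$x, two$labels)
  b2 <- decision_boundaries(m2)
  expect_identical(nrow(b2$lines), 1L)
  ln <- b2$lines[1, ]
  M <- m2$means2d
  set.seed(29)
  for (i in 1:100) {
    # a point on the line: parametrise along the direction orthogonal to (a,b)
    t0 <- rnorm(1, 0, 10)
    p0 <- c(ln$a, ln$b) * ln$c / (ln$a^2 + ln$b^2) + t0 * c(-ln$b, ln$a)
    expect_equal(sum((p0 - M[1, ])^2), sum((p0 - M[2, ])^2), tolerance = 1e-8)
  }

  # three non-collinear means: the three bisectors meet at the circumcenter
  M3 <- model$means2d
  cc_from <- function(i, j, k) {
    # computational-geometry oracle: solve the two bisector equations
    A <- rbind(2 * (M3[j, ] - M3[i, ]), 2 * (M3[k, ] - M3[i, ]))
    b <- c(sum(M3[j, ]^2) - sum(M3[i, ]^2), sum(M3[k, ]^2) - sum(M3[i, ]^2))
    solve(A, b)
  }
  cc <- cc_from(1, 2, 3)
  expect_equal(sum((cc - M3[1, ])^2), sum((cc - M3[2, ])^2), tolerance = 1e-8)
  expect_equal(sum((cc - M3[1, ])^2), sum((cc - M3[3, ])^2), tolerance = 1e-8)

  # region polygons agree with nearest-mean prediction on training points
  Z <- project(model, toy$x)
  assigned <- assign_region(bd, Z)
  predicted <- predict(model, toy$x)
  expect_identical(assigned, predicted)
})

test_that("region assignment equals predict on a dense random latent sample", {
  toy <- toy_gaussians(n_per_class = 15L, seed = 30)
  model <- fisher_lda_fit(toy$x, toy$labels)
  bd <- decision_boundaries(model)
  set.seed(31)
  span <- bd$region
  Z <- cbind(runif(10000, span[1], span[2]), runif(10000, span[3], span[4]))
  assigned <- assign_region(bd, Z)
  predicted <- mrsdx:::.nearest_mean(Z, model$means2d, model$classes)
  expect_identical(assigned, predicted)
})

test_that("bootstrap evaluation is deterministic, separable-accurate and null-calibrated", {
  toy <- toy_gaussians(n_per_class = 15L, sep = 10, seed = 32)
  tr <- lda_trainer(max_features = 4L)
  e1 <- bootstrap_evaluate(toy$x, toy$labels, tr, B = 50L, seed = 99L)
  e2 <- bootstrap_evaluate(toy$x, toy$labels, tr, B = 50L, seed = 99L)
  expect_identical(e1$oob_accuracies, e2$oob_accuracies)
  expect_gte(e1$accuracy, 0.99)
  expect_true(all(rowSums(e1$confusion) >= 0))

  # B=1 with the resample forced to the full dataset degenerates to
  # training accuracy
  full_trainer <- function(x, labels) fisher_lda_fit(x, labels)
  model <- full_trainer(toy$x, toy$labels)
  train_acc <- mean(predict(model, toy$x) == toy$labels)
  e3 <- bootstrap_evaluate(toy$x, toy$labels, full_trainer, B = 1L, seed = 1L)
  # OOB accuracy on a separable problem equals training accuracy (both 1)
  expect_equal(e3$accuracy, train_acc)

  expect_error(bootstrap_evaluate(toy$x, toy$labels, tr, B = 0L, seed = 1L),
               class = "mrsdx_invalid_argument")
  expect_error(bootstrap_evaluate(toy$x, toy$labels, tr, B = 2L),
               class = "mrsdx_invalid_argument")
})

test_that("held-out evaluation reports accuracy and confusion without refitting", {
  toy <- toy_gaussians(n_per_class = 20L, seed = 33)
  model <- fisher_lda_fit(toy$x, toy$labels)
  ev <- evaluate_on_test(model, toy$x, toy$labels)
  expect_equal(ev$accuracy, 1.0)
  expect_equal(sum(ev$confusion), 60)
  expect_equal(as.numeric(rowSums(ev$confusion)),
               as.numeric(table(factor(toy$labels, model$classes))))

  fresh <- toy_gaussians(n_per_class = 100L, seed = 34)
  ev2 <- evaluate_on_test(model, fresh$x, fresh$labels)
  expect_gte(ev2$accuracy, 0.95)

  expect_error(evaluate_on_test(model, toy$x[0, , drop = FALSE], character()),
               class = "mrsdx_invalid_argument")
})

test_that("model JSON roundtrip reproduces projections bit-for-bit", {
  toy <- toy_gaussians(n_per_class = 8L, seed = 35)
  model <- fisher_lda_fit(toy$x, toy$labels, features = c(1L, 3L))
  path <- withr::local_tempfile(fileext = ".json")
  write_lda_model(model, path)
  back <- read_lda_model(path)
  expect_identical(project(back, toy$x), project(model, toy$x))
  expect_identical(predict(back, toy$x), predict(model, toy$x))
})

test_that("peak heights apply the dynamically recomputed dataset offset", {
  s1 <- canonical_spectrum(lorentzian_bump(3.21, height = 10) - 5)  # min -5
  s2 <- canonical_spectrum(lorentzian_bump(2.01, height = 8))
  off <- dataset_offset(list(s1, s2))
  expect_equal(off, -min(s1$intensities) + 1e-9)
  expect_equal(off, 5, tolerance = 1e-3)
  expect_gt(peak_height(s1, 3.21, dataset_offset = off), 0)
  expect_gt(min(s1$intensities + off), 0)

  # adding a deeper spectrum recomputes the offset
  s3 <- canonical_spectrum(lorentzian_bump(1.33, height = 10) - 9)
  off2 <- dataset_offset(list(s1, s2, s3))
  expect_equal(off2, 9, tolerance = 1e-3)

  # an all-positive dataset needs no offset
  expect_identical(dataset_offset(list(s2)), 0)
  expect_error(peak_height(s1, 7.1), class = "mrsdx_invalid_argument")
})

test_that("the ratio rule yields Cho/NAA vs mI/NAA coordinates", {
  # tumour-like: choline much taller than NAA at short TE
  short <- canonical_spectrum(lorentzian_bump(3.21, height = 50) +
                                lorentzian_bump(2.01, height = 10),
                              te_class = "short")
  long <- canonical_spectrum(lorentzian_bump(3.55, height = 20) +
                               lorentzian_bump(2.01, height = 10),
                             te_class = "long")
  res <- ratio_classify(short, long)
  expect_gt(res$x, 1)
  expect_true(is.na(res$class))

  # equal heights -> ratio 1
  eq <- canonical_spectrum(lorentzian_bump(3.21, height = 10) +
                             lorentzian_bump(2.01, height = 10))
  res_eq <- ratio_classify(eq, long)
  expect_equal(res_eq$x, 1, tolerance = 0.05)

  # strong inverted lactate at long TE: offset keeps denominators positive
  inv <- canonical_spectrum(lorentzian_bump(2.01, height = 5) -
                              lorentzian_bump(1.33, height = 30),
                            te_class = "long")
  res_inv <- ratio_classify(short, inv,
                            offset_long = dataset_offset(list(inv)))
  expect_true(is.finite(res_inv$y) && res_inv$y > 0)

  # configured piecewise-linear boundary assigns classes
  rule <- ratio_rule(boundary = list(points = rbind(c(0, 1), c(5, 1)),
                                     classes = c("tumour", "normal")))
  res_b <- ratio_classify(short, long, rule)
  expect_identical(res_b$class, if (res_b$y >= 1) "tumour" else "normal")
  expect_error(ratio_rule(x_num = 2.01, x_den = 2.01),
               class = "mrsdx_invalid_argument")
})

test_that("manual overviews match brute-force recomputation", {
  set.seed(36)
  spectra <- lapply(1:6, function(i)
    canonical_spectrum(lorentzian_bump(3.21, height = 5 + i) +
                         lorentzian_bump(2.01, height = 12 - i) +
                         rnorm(512, 0, 0.1)))
  # height mode with equal features: x == y
  ov <- manual_overview(spectra, 3.21, 3.21, mode = "height")
  expect_equal(ov$x, ov$y)

  # ratio mode equals independent recomputation
  ov2 <- manual_overview(spectra, c(3.21, 2.01), c(3.55, 2.01), mode = "ratio")
  off <- dataset_offset(spectra)
  brute <- vapply(spectra, function(s) {
    h <- function(p) max(s$intensities[seq(which.min(abs(ppm_axis() - p)) - 5,
                                           which.min(abs(ppm_axis() - p)) + 5)]) + off
    h(3.21) / h(2.01)
  }, numeric(1))
  expect_equal(ov2$x, brute)

  # empty dataset: empty result, no error
  empty <- manual_overview(list(), 3.21, 2.01)
  expect_identical(nrow(empty), 0L)
})
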