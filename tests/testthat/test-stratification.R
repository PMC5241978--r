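proto2 <- prototype_set(rbind(A = c(0, 0), B = c(4, 0)))

test_that("prototype_set and membership enforce invariants", {
  expect_error(prototype_set(rbind(c(0, 0), c(1, 1)), c("A", "A")),
               "unique")
  expect_error(prototype_set(rbind(c(0, 0)), "A", priors = c(0.5)),
               "sum to 1")
  expect_error(membership(c(0.5, 0.6), c("A", "B")), "sum to 1")
  expect_error(membership(c(-0.1, 1.1), c("A", "B")), "non-negative")
})

test_that("hard_assign picks the nearest centroid, ties to earlier label", {
  expect_equal(hard_assign(c(0, 0), proto2), "A")   # at centroid A
  expect_equal(hard_assign(c(2, 5), proto2), "A")   # exact midline tie
  expect_equal(hard_assign(c(3.9, 0), proto2), "B")
  expect_error(hard_assign(c(1, 2, 3), proto2), "dimension")
  # brute-force distance minimisation on random centroids
  set.seed(5)
  ps <- prototype_set(matrix(rnorm(5 * 4), 5, 4),
                      labels = paste0("K", 1:5))
  for (rep in 1:50) {
    x <- rnorm(4)
    dd <- vapply(1:5, function(k)
      oracle_dist(x, ps$centroids[k, ]), numeric(1))
    expect_equal(hard_assign(x, ps), ps$labels[which.min(dd)])
  }
})

test_that("soft_assign follows the Gaussian-kernel formula and limits", {
  # d = (1, 2) at temperature 1: exp(-1/2), exp(-2) renormalized
  ps <- prototype_set(rbind(A = c(1, 0), B = c(2, 0)))
  m <- soft_assign(c(0, 0), ps, temperature = 1)
  z <- exp(-0.5) + exp(-2)
  expect_equal(as.numeric(m), c(exp(-0.5) / z, exp(-2) / z),
               tolerance = 1e-12)
  # equidistant -> (0.5, 0.5) at any temperature
  for (temp in c(0.1, 1, 50))
    expect_equal(as.numeric(soft_assign(c(2, 3), proto2, temp)),
                 c(0.5, 0.5), tolerance = 1e-12)
  # temperature -> 0: one-hot at the nearest centroid
  m0 <- soft_assign(c(0.1, 0), proto2, temperature = 1e-6)
  expect_gte(m0[1, "A"], 1 - 1e-9)
  # temperature -> Inf: uniform
  mI <- soft_assign(c(0.1, 0), proto2, temperature = 1e8)
  expect_equal(as.numeric(mI), c(0.5, 0.5), tolerance = 1e-6)
  expect_error(soft_assign(c(0, 0), proto2, temperature = 0),
               "positive")
})

test_that("argmax of soft_assign agrees with hard_assign (property)", {
  set.seed(14)
  ps <- prototype_set(matrix(rnorm(4 * 3), 4, 3),
                      labels = c("A", "B", "C", "D"))
  x <- matrix(rnorm(200 * 3), 200, 3)
  m <- soft_assign(x, ps, temperature = 0.7)
  expect_true(all(abs(rowSums(m) - 1) < 1e-9))
  expect_true(all(m >= 0))
  expect_equal(ps$labels[max.col(unclass(m), ties.method = "first")],
               hard_assign(x, ps))
  # rigid translation invariance
  shift <- rnorm(3)
  ps_s <- prototype_set(sweep(ps$centroids, 2, -shift), ps$labels)
  m_s <- soft_assign(sweep(x, 2, -shift), ps_s, temperature = 0.7)
  expect_equal(unclass(m_s), unclass(m), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("apply_prior is a renormalized Bayes product", {
  m <- membership(c(0.7, 0.3), c("A", "B"))
  # hand-computed: (0.7 * 0.25, 0.3 * 0.75) / 0.4 = (0.4375, 0.5625)
  post <- apply_prior(m, c(0.25, 0.75))
  expect_equal(as.numeric(post), c(0.4375, 0.5625), tolerance = 1e-12)
  # uniform prior is the identity
  expect_equal(unclass(apply_prior(m, c(0.5, 0.5))), unclass(m),
               tolerance = 1e-12)
  # degenerate prior concentrates all mass
  expect_equal(as.numeric(apply_prior(m, c(1, 0))), c(1, 0))
  # disjoint support errors
  hot <- membership(c(0, 1), c("A", "B"))
  expect_error(apply_prior(hot, c(1, 0)), "degenerate")
  set.seed(31)
  for (rep in 1:20) {
    mm <- random_membership(5, 3)
    expect_equal(unclass(apply_prior(mm, rep(1 / 3, 3))), unclass(mm),
                 tolerance = 1e-12)
  }
})

test_that("fit_discriminant reproduces textbook Fisher LDA", {
  set.seed(61)
  n <- 100
  x <- rbind(matrix(rnorm(n * 2, -1.5), n, 2),
             matrix(rnorm(n * 2, 1.5), n, 2))
  y <- rep(c("pos", "neg"), each = n)
  ld <- fit_discriminant(x, y, positive_label = "pos")
  ref <- oracle_fisher(x, y, "pos")
  # same decision function up to positive scaling
  scale_ratio <- ld$weights[1] / ref$weights[1]
  expect_gt(scale_ratio, 0)
  expect_equal(ld$weights / scale_ratio, ref$weights, tolerance = 1e-8)
  expect_equal(ld$offset / scale_ratio, ref$offset, tolerance = 1e-8)
  # >= 99% agreement with the oracle rule; separable -> 0 training error
  agree <- mean((x %*% ld$weights + ld$offset >= 0) ==
                  (x %*% ref$weights + ref$offset >= 0))
  expect_gte(agree, 0.99)
  # symmetric classes at (-1, 0) / (1, 0): boundary is x1 = 0
  xs <- rbind(c(-1, 0), c(-1, 1), c(-1, -1), c(1, 0), c(1, 1),
              c(1, -1))
  lds <- fit_discriminant(xs, rep(c("L", "R"), each = 3),
                          positive_label = "R")
  expect_equal(lds$weights[2], 0, tolerance = 1e-12)
  expect_equal(lds$offset, 0, tolerance = 1e-12)
  # relabelling the classes negates weights and offset
  flip <- fit_discriminant(x, y, positive_label = "neg")
  expect_equal(flip$weights, -ld$weights, tolerance = 1e-9)
  expect_equal(flip$offset, -ld$offset, tolerance = 1e-9)
  expect_error(fit_discriminant(x, rep("pos", 2 * n)), "two classes")
  expect_error(fit_discriminant(x[1:3, ], c("a", "a", "b")), ">= 2")
})

test_that("perfectly separable planted data give zero training error", {
  set.seed(62)
  x <- rbind(matrix(rnorm(100 * 3, 0, 0.5), 100, 3),
             matrix(rnorm(100 * 3, 8, 0.5), 100, 3))
  y <- rep(c("lo", "hi"), each = 100)
  ld <- fit_discriminant(x, y, positive_label = "hi")
  expect_equal(mean(classify_side(x, ld) == y), 1)
})

test_that("classify_side obeys the boundary and antisymmetry rules", {
  ld <- structure(list(weights = c(1, 0), offset = 0,
                       positive_label = "P", negative_label = "N"),
                  class = "linear_discriminant")
  expect_equal(classify_side(c(0, 3), ld), "P")   # boundary -> positive
  expect_equal(classify_side(c(-1, 0), ld), "N")
  neg <- ld; neg$weights <- -ld$weights; neg$offset <- -ld$offset
  set.seed(4)
  for (rep in 1:25) {
    x <- rnorm(2)
    if (abs(sum(ld$weights * x) + ld$offset) < 1e-9) next
    expect_false(classify_side(x, ld) == classify_side(x, neg))
  }
  # singular within-class covariance is ridge-regularized, not fatal
  xs <- rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1)) +
    cbind(rnorm(4, 0, 1e-3), 0)
  expect_s3_class(fit_discriminant(xs, c("a", "a", "b", "b")),
                  "linear_discriminant")
})
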