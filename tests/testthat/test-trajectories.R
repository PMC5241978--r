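one_hot <- function(idx, labels) {
  m <- matrix(0, length(idx), length(labels))
  m[cbind(seq_along(idx), idx)] <- 1
  membership(m, labels)
}

test_that("hard counting reproduces deterministic and ratio fixtures", {
  t1 <- one_hot(c(1, 1, 1), c("A", "B"))
  t2 <- one_hot(c(1, 1, 1), c("1", "2", "3"))
  m <- suppressWarnings(
    estimate_transition(t1, t2, mode = "hard", smoothing_alpha = 0))
  expect_warning(
    estimate_transition(t1, t2, mode = "hard", smoothing_alpha = 0),
    "uniform")                       # row B never observed
  expect_equal(unname(m$cpt["A", ]), c(1, 0, 0))
  expect_equal(unname(m$cpt["B", ]), rep(1 / 3, 3))
  # 2 patients A->1 and A->2: row A = (0.5, 0.5, 0)
  m2 <- suppressWarnings(estimate_transition(
    one_hot(c(1, 1), c("A", "B")), one_hot(c(1, 2), c("1", "2", "3")),
    mode = "hard", smoothing_alpha = 0))
  expect_equal(unname(m2$cpt["A", ]), c(0.5, 0.5, 0))
  expect_equal(unname(m2$t1_marginal), c(1, 0))
  expect_error(estimate_transition(t1, one_hot(1, "1")), "different")
})

test_that("soft counting matches the brute-force double sum", {
  set.seed(18)
  m1 <- random_membership(20, 3, c("A", "B", "C"))
  m2 <- random_membership(20, 5, as.character(1:5))
  model <- estimate_transition(m1, m2, mode = "soft",
                               smoothing_alpha = 0)
  expect_equal(unname(model$cpt), oracle_soft_cpt(unclass(m1),
                                                  unclass(m2)),
               tolerance = 1e-12)
  expect_true(all(abs(rowSums(model$cpt) - 1) < 1e-9))
  # smoothing keeps rows stochastic
  sm <- estimate_transition(m1, m2, mode = "soft", smoothing_alpha = 2)
  expect_true(all(abs(rowSums(sm$cpt) - 1) < 1e-9))
  expect_true(all(sm$cpt > 0))
})

test_that("hard and soft estimation coincide on one-hot memberships", {
  set.seed(19)
  i <- sample(3, 40, replace = TRUE)
  j <- sample(5, 40, replace = TRUE)
  h <- estimate_transition(one_hot(i, c("A", "B", "C")),
                           one_hot(j, as.character(1:5)),
                           mode = "hard", smoothing_alpha = 0.5)
  s <- estimate_transition(one_hot(i, c("A", "B", "C")),
                           one_hot(j, as.character(1:5)),
                           mode = "soft", smoothing_alpha = 0.5)
  expect_equal(h$cpt, s$cpt, tolerance = 1e-12)
  expect_equal(h$counts, s$counts, tolerance = 1e-12)
})

test_that("predict marginalizes soft evidence over the CPT", {
  set.seed(23)
  m1 <- random_membership(10, 3, c("A", "B", "C"))
  m2 <- random_membership(10, 5, as.character(1:5))
  model <- estimate_transition(m1, m2, mode = "soft",
                               smoothing_alpha = 0.1)
  # one-hot evidence returns the CPT row exactly
  pB <- predict(model, c(0, 1, 0))
  expect_equal(as.numeric(pB), unname(model$cpt["B", ]),
               tolerance = 1e-12)
  # 50/50 evidence is the mean of two rows
  pAB <- predict(model, c(0.5, 0.5, 0))
  expect_equal(as.numeric(pAB),
               unname((model$cpt["A", ] + model$cpt["B", ]) / 2),
               tolerance = 1e-12)
  # direct-evaluation oracle and linearity
  for (rep in 1:10) {
    ev <- as.numeric(random_membership(1, 3))
    want <- vapply(1:5, function(j) sum(ev * model$cpt[, j]),
                   numeric(1))
    got <- as.numeric(predict(model, ev))
    expect_equal(got, want, tolerance = 1e-12)
    expect_equal(sum(got), 1, tolerance = 1e-9)
    ev2 <- as.numeric(random_membership(1, 3))
    lam <- runif(1)
    lhs <- as.numeric(predict(model, lam * ev + (1 - lam) * ev2))
    rhs <- lam * as.numeric(predict(model, ev)) +
      (1 - lam) * as.numeric(predict(model, ev2))
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
  expect_error(predict(model, membership(c(0.5, 0.5), c("X", "Y"))),
               "labels")
})

test_that("trajectory_graph filters and orders edges", {
  cpt <- rbind(A = c(0.7, 0.2, 0.1), B = c(0.05, 0.15, 0.8))
  colnames(cpt) <- as.character(1:3)
  model <- structure(list(t1_labels = c("A", "B"),
                          t2_labels = as.character(1:3), cpt = cpt,
                          t1_marginal = c(A = 0.5, B = 0.5),
                          counts = cpt, mode = "hard",
                          smoothing_alpha = 0),
                     class = "transition_model")
  all_edges <- trajectory_graph(model, 0)
  expect_equal(nrow(all_edges), 6L)
  some <- trajectory_graph(model, 0.2)
  expect_equal(some$probability, c(0.7, 0.2, 0.8))  # by t1, then desc
  expect_equal(some$t1, c("A", "A", "B"))
  none <- trajectory_graph(model, 1.0)
  expect_equal(nrow(none), 0L)
  expect_error(trajectory_graph(model, 1.5), "\\[0, 1\\]")
})

test_that("transition models round-trip through JSON", {
  set.seed(29)
  model <- estimate_transition(random_membership(15, 3, c("A", "B", "C")),
                               random_membership(15, 5,
                                                 as.character(1:5)),
                               mode = "soft", smoothing_alpha = 0.5)
  path <- tempfile(fileext = ".json")
  write_transition_model(model, path)
  back <- read_transition_model(path)
  expect_equal(back$cpt, model$cpt, tolerance = 1e-12)
  expect_equal(back$counts, model$counts, tolerance = 1e-12)
  expect_equal(back$t1_marginal, model$t1_marginal, tolerance = 1e-12)
  expect_equal(back$mode, model$mode)
  unlink(path)
})

test_that("planted 3->5 transition is recovered within 0.08", {
  transition <- rbind(c(0.60, 0.20, 0.10, 0.05, 0.05),
                      c(0.10, 0.50, 0.20, 0.10, 0.10),
                      c(0.05, 0.05, 0.20, 0.30, 0.40))
  errs <- vapply(1:5, function(seed) {
    spec <- two_timepoint_spec(
      mixture_spec(750, 5, 3, separation = 8, seed = NULL),
      transition, t2_within_sd = 1, seed = seed)
    sim <- simulate_two_timepoint(spec)
    m1 <- one_hot(sim$labels_t1, c("A", "B", "C"))
    m2 <- one_hot(sim$labels_t2, as.character(1:5))
    est <- estimate_transition(m1, m2, mode = "hard",
                               smoothing_alpha = 0)
    max(abs(est$cpt - transition))
  }, numeric(1))
  expect_lte(mean(errs), 0.08)
})
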