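test_that("clustering_config validates its parameters", {
  expect_error(clustering_config(dc_value = 1.5), "\\(0, 1\\)")
  expect_error(clustering_config(dc_mode = "absolute", dc_value = -1),
               "> 0")
  expect_error(clustering_config(selection = "fixed_k"), "integer k")
  expect_error(clustering_config(k = 3), "fixed_k")
})

test_that("rho counts neighbours inside d_c (triangle fixtures)", {
  # equilateral triangle at distance 1
  d <- matrix(1, 3, 3); diag(d) <- 0
  cfg <- function(dc) clustering_config(dc_mode = "absolute",
                                        dc_value = dc)
  expect_equal(compute_rho(d, cfg(1.5)), c(2, 2, 2))
  expect_equal(compute_rho(d, cfg(0.5)), c(0, 0, 0))
  # boundary is exclusive: d == d_c does not count
  expect_equal(compute_rho(d, cfg(1)), c(0, 0, 0))
  expect_error(compute_rho(matrix(c(0, 1, 2, 0), 2, 2), cfg(1)),
               "symmetric")
  expect_error(compute_rho(-d, cfg(1)), "negative")
})

test_that("rho and delta match brute-force oracles on random data", {
  set.seed(101)
  for (kernel in c("hard", "gaussian")) {
    x <- matrix(rnorm(50 * 2), 50, 2)
    d <- as.matrix(dist(x)); dimnames(d) <- NULL
    cfg <- clustering_config(dc_value = 0.1, kernel = kernel)
    dc <- resolve_dc(d, cfg)
    expect_equal(compute_rho(d, cfg), oracle_rho(d, dc, kernel),
                 tolerance = 1e-12)
    rho <- compute_rho(d, cfg)
    got <- compute_delta(d, rho)
    want <- oracle_delta(d, rho)
    expect_equal(got$delta, want$delta, tolerance = 1e-12)
    expect_equal(got$nearest_higher, want$nearest_higher)
  }
})

test_that("delta conventions: global maximum, two points, rho ties", {
  # two points: denser one takes the max convention, other the min
  d <- matrix(c(0, 3, 3, 0), 2, 2)
  r <- compute_delta(d, rho = c(5, 1))
  expect_equal(r$delta, c(3, 3))
  expect_equal(r$nearest_higher, c(NA_integer_, 1L))
  # full rho tie: index order is the density order
  r2 <- compute_delta(d, rho = c(2, 2))
  expect_equal(r2$nearest_higher, c(NA_integer_, 1L))
  # unique global max gets its maximum pairwise distance
  set.seed(8)
  x <- matrix(rnorm(20 * 3), 20, 3)
  dm <- as.matrix(dist(x)); dimnames(dm) <- NULL
  rho <- compute_rho(dm, clustering_config(dc_value = 0.2))
  top <- order(-rho, seq_len(20))[1]
  dl <- compute_delta(dm, rho)
  expect_equal(dl$delta[top], max(dm[top, -top]))
})

test_that("prototype selection rules behave as specified", {
  rho <- c(10, 9, 1, 2, 3, 1)
  delta <- c(5, 4, 0.1, 0.2, 0.1, 0.05)
  gamma <- (rho - 1) / 9 * ((delta - 0.05) / 4.95)
  ord <- order(-gamma, seq_along(gamma))
  cfgk <- function(k) clustering_config(selection = "fixed_k", k = k)
  expect_equal(select_prototypes(rho, delta, cfgk(3)), ord[1:3])
  expect_error(select_prototypes(rho, delta, cfgk(9)), "exceeds")
  # gamma_gap finds the planted two-prototype structure
  gg <- select_prototypes(rho, delta, clustering_config())
  expect_equal(sort(gg), c(1L, 2L))
  # degenerate input: all points identical -> exactly one prototype
  x0 <- matrix(1, 5, 2)
  res0 <- dp_cluster(x0, clustering_config(dc_mode = "absolute",
                                           dc_value = 1))
  expect_length(res0$prototypes, 1L)
  expect_true(all(res0$labels == 1L))
})

test_that("gamma_gap separates two planted blobs in >= 95/100 seeds", {
  hits <- 0L
  for (seed in 1:100) {
    sim <- simulate_mixture(mixture_spec(100, 2, 2, separation = 10,
                                         seed = seed))
    res <- dp_cluster(sim$cohort)
    ok <- length(res$prototypes) == 2L &&
      length(unique(sim$labels[res$prototypes])) == 2L
    hits <- hits + ok
  }
  expect_gte(hits, 95L)
})

test_that("labels assign each point to its nearest prototype", {
  # two distant pairs, fixed_k = 2
  x <- rbind(c(0, 0), c(0, 1), c(100, 0), c(100, 1))
  res <- dp_cluster(x, clustering_config(selection = "fixed_k", k = 2))
  expect_equal(res$labels[1], res$labels[2])
  expect_equal(res$labels[3], res$labels[4])
  expect_equal(length(unique(res$labels)), 2L)
  # brute-force nearest-prototype check on random data
  set.seed(77)
  y <- matrix(rnorm(60 * 4), 60, 4)
  r <- dp_cluster(y, clustering_config(selection = "fixed_k", k = 5))
  for (i in seq_len(nrow(y))) {
    dd <- vapply(r$prototypes, function(p) oracle_dist(y[i, ], y[p, ]),
                 numeric(1))
    expect_equal(r$labels[i], which.min(dd))
  }
  # partition invariants
  expect_equal(sort(unique(r$labels)), seq_along(r$prototypes))
  expect_equal(r$labels[r$prototypes], seq_along(r$prototypes))
})

test_that("duplicating every point preserves prototypes and partition", {
  set.seed(12)
  sim <- simulate_mixture(mixture_spec(40, 2, 2, separation = 9,
                                       seed = 12))
  x <- signature_matrix(sim$cohort)
  # fixed absolute radius: fraction-mode d_c would shift when the
  # duplicate zero-distance pairs enter the quantile pool
  cfg <- clustering_config(dc_mode = "absolute", dc_value = 1.5,
                           selection = "fixed_k", k = 2)
  base <- dp_cluster(x, cfg)
  dup <- dp_cluster(rbind(x, x), cfg)
  expect_setequal(
    apply(dup$centroids, 1, paste, collapse = ","),
    apply(base$centroids, 1, paste, collapse = ","))
  relabel <- dup$labels[seq_len(nrow(x))]
  expect_equal(adjusted_rand_index(relabel, base$labels), 1)
  expect_equal(dup$labels[seq_len(nrow(x))],
               dup$labels[nrow(x) + seq_len(nrow(x))])
})

test_that("pipeline is deterministic and rho permutation-equivariant", {
  set.seed(9)
  x <- matrix(rnorm(40 * 3), 40, 3)
  cfg <- clustering_config()
  expect_identical(dp_cluster(x, cfg), dp_cluster(x, cfg))
  d <- as.matrix(dist(x)); dimnames(d) <- NULL
  rho <- compute_rho(d, cfg)
  perm <- sample(40)
  rho_p <- compute_rho(d[perm, perm], cfg)
  expect_equal(rho_p, rho[perm], tolerance = 1e-12)
})

test_that("non-prototype delta <= lowest prototype delta under fixed_k", {
  set.seed(21)
  for (rep in 1:5) {
    x <- matrix(rnorm(50 * 2) + rep(c(0, 6), each = 25), 50, 2)
    res <- dp_cluster(x, clustering_config(kernel = "gaussian",
                                           selection = "fixed_k",
                                           k = 2))
    gs <- sort(res$gamma, decreasing = TRUE)
    if (gs[2] <= gs[3]) next  # guard: k-th rank must be unambiguous
    expect_lte(max(res$delta[-res$prototypes]) - 1e-12,
               min(res$delta[res$prototypes]))
  }
})

test_that("chain assignment matches nearest assignment on round blobs", {
  sim <- simulate_mixture(mixture_spec(80, 2, 2, separation = 10,
                                       seed = 3))
  x <- signature_matrix(sim$cohort)
  a <- dp_cluster(x, clustering_config(selection = "fixed_k", k = 2))
  b <- dp_cluster(x, clustering_config(selection = "fixed_k", k = 2,
                                       assign = "chain"))
  expect_equal(adjusted_rand_index(a$labels, b$labels), 1)
})

test_that("adjusted_rand_index sanity", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_lt(abs(adjusted_rand_index(rep(1:2, 50),
                                    rep(1:2, each = 50))), 0.2)
})
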