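# Independent brute-force oracles used by the equivalence tests.
# Deliberately written as naive double loops so they share no code path
# with the package implementation.

oracle_dist <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  sqrt(s)
}

oracle_dist_matrix <- function(x) {
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- oracle_dist(x[i, ], x[j, ])
  d
}

oracle_rho <- function(d, dc, kernel = "hard") {
  n <- nrow(d)
  rho <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    rho[i] <- rho[i] +
      if (kernel == "hard") as.numeric(d[i, j] < dc) else
        exp(-(d[i, j] / dc)^2)
  }
  rho
}

# total density order: rho descending, index ascending
oracle_delta <- function(d, rho) {
  n <- nrow(d)
  delta <- numeric(n)
  nearest <- rep(NA_integer_, n)
  denser <- function(j, i) rho[j] > rho[i] || (rho[j] == rho[i] && j < i)
  for (i in seq_len(n)) {
    best <- Inf; who <- NA_integer_
    for (j in seq_len(n)) {
      if (j == i || !denser(j, i)) next
      if (d[i, j] < best) { best <- d[i, j]; who <- j }
    }
    if (is.na(who)) {
      delta[i] <- max(d[i, -i])
    } else {
      delta[i] <- best; nearest[i] <- who
    }
  }
  list(delta = delta, nearest_higher = nearest)
}

oracle_soft_cpt <- function(m1, m2) {
  k1 <- ncol(m1); k2 <- ncol(m2)
  counts <- matrix(0, k1, k2)
  for (p in seq_len(nrow(m1)))
    for (i in seq_len(k1)) for (j in seq_len(k2))
      counts[i, j] <- counts[i, j] + m1[p, i] * m2[p, j]
  counts / rowSums(counts)
}

# textbook Fisher LDA, written independently
oracle_fisher <- function(x, y, pos) {
  xp <- x[y == pos, , drop = FALSE]
  xn <- x[y != pos, , drop = FALSE]
  mp <- apply(xp, 2, mean); mn <- apply(xn, 2, mean)
  cp <- cov(xp) * (nrow(xp) - 1)
  cn <- cov(xn) * (nrow(xn) - 1)
  sw <- (cp + cn) / (nrow(x) - 2)
  w <- solve(sw) %*% (mp - mn)
  b <- -as.numeric(t(w) %*% (mp + mn)) / 2
  list(weights = as.numeric(w), offset = b)
}

random_membership <- function(n, k, labels = paste0("L", seq_len(k))) {
  m <- matrix(rexp(n * k), n, k)
  membership(m / rowSums(m), labels)
}

toy_scale <- function(d = 3, range = NULL) {
  scale_definition("toy", paste0("it", seq_len(d)), item_range = range)
}
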