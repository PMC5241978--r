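#' Configuration for density-peak clustering
#'
#' Controls the neighbourhood radius `d_c`, the density kernel, and the
#' rule that decides how many of the high-`gamma` points become
#' prototypes.
#'
#' @param dc_mode `"fraction"`: `dc_value` is a quantile in (0, 1) of the
#'   off-diagonal pairwise distances (default 0.02, i.e. a ~2%%
#'   neighbourhood); `"absolute"`: `dc_value` is the radius itself (> 0).
#' @param dc_value Numeric, interpreted per `dc_mode`.
#' @param kernel `"hard"` counts neighbours strictly inside `d_c`;
#'   `"gaussian"` uses the smooth weight `exp(-(d/d_c)^2)` (useful at
#'   small n where integer counts tie heavily).
#' @param selection Prototype selection rule: `"gamma_gap"` (cut at the
#'   largest consecutive ratio gap in sorted `gamma`), `"threshold"`
#'   (`gamma > mean + threshold_multiplier * sd`), or `"fixed_k"` (top
#'   `k`).
#' @param k Number of prototypes; required iff `selection = "fixed_k"`.
#' @param threshold_multiplier Multiplier for the `"threshold"` rule.
#' @param assign `"nearest"` labels every point by its nearest prototype
#'   (the default); `"chain"` propagates labels down the
#'   nearest-higher-density links, which can differ on elongated clusters.
#' @param seed Integer recorded with results (the pipeline itself is
#'   deterministic).
#' @return An object of class `clustering_config`.
#' @export
clustering_config <- function(dc_mode = c("fraction", "absolute"),
                              dc_value = 0.02,
                              kernel = c("hard", "gaussian"),
                              selection = c("gamma_gap", "threshold",
                                            "fixed_k"),
                              k = NULL,
                              threshold_multiplier = 2,
                              assign = c("nearest", "chain"),
                              seed = NULL) {
  dc_mode <- match.arg(dc_mode)
  kernel <- match.arg(kernel)
  selection <- match.arg(selection)
  assign <- match.arg(assign)
  dc_value <- as.numeric(dc_value)
  if (dc_mode == "fraction" && !(dc_value > 0 && dc_value < 1))
    stop("fraction-mode dc_value must lie in (0, 1)", call. = FALSE)
  if (dc_mode == "absolute" && !(dc_value > 0))
    stop("absolute-mode dc_value must be > 0", call. = FALSE)
  if (selection == "fixed_k") {
    if (is.null(k) || length(k) != 1L || k < 1 || k != round(k))
      stop("selection 'fixed_k' requires a positive integer k",
           call. = FALSE)
    k <- as.integer(k)
  } else if (!is.null(k)) {
    stop("k is only meaningful with selection 'fixed_k'", call. = FALSE)
  }
  structure(list(dc_mode = dc_mode, dc_value = dc_value, kernel = kernel,
                 selection = selection, k = k,
                 threshold_multiplier = as.numeric(threshold_multiplier),
                 assign = assign, seed = seed),
            class = "clustering_config")
}

check_distance_matrix <- function(distances) {
  distances <- as.matrix(distances)
  n <- nrow(distances)
  if (n != ncol(distances) || n < 2L)
    stop("distance matrix must be square with n >= 2", call. = FALSE)
  if (any(distances < 0))
    stop("distance matrix has negative entries", call. = FALSE)
  if (any(abs(diag(distances)) > 1e-12))
    stop("distance matrix diagonal must be zero", call. = FALSE)
  if (max(abs(distances - t(distances))) > 1e-8)
    stop("distance matrix is not symmetric", call. = FALSE)
  distances
}

#' Resolve the neighbourhood radius d_c
#'
#' In fraction mode `d_c` is the `dc_value` quantile of the off-diagonal
#' pairwise distances; in absolute mode it is `dc_value` itself.
#'
#' @param distances Symmetric distance matrix with zero diagonal.
#' @param config A [clustering_config].
#' @return Scalar radius.
#' @export
resolve_dc <- function(distances, config) {
  distances <- check_distance_matrix(distances)
  if (config$dc_mode == "absolute") return(config$dc_value)
  off <- distances[lower.tri(distances)]
  as.numeric(stats::quantile(off, probs = config$dc_value, names = FALSE))
}

#' Local density rho of every point
#'
#' With the hard kernel, `rho_i` is the number of other points strictly
#' inside radius `d_c` of point i; with the gaussian kernel it is
#' `sum_{j != i} exp(-(d_ij/d_c)^2)`.
#'
#' @inheritParams resolve_dc
#' @return Numeric vector of length n.
#' @export
compute_rho <- function(distances, config = clustering_config()) {
  distances <- check_distance_matrix(distances)
  dc <- resolve_dc(distances, config)
  if (config$kernel == "hard") {
    w <- distances < dc
  } else {
    w <- exp(-(distances / dc)^2)
  }
  diag(w) <- 0
  rowSums(w)
}

#' Separation delta and nearest higher-density neighbour
#'
#' For each point, `delta_i` is the minimum distance to any point of
#' higher local density, and `nearest_higher_i` the index attaining it
#' (ties broken by lowest index).  Density ties are resolved by treating
#' the lower-index point as denser, giving a strict total order.  The
#' point of globally maximal density gets `delta = max_j d_ij` and the
#' sentinel `NA` as its neighbour.
#'
#' @inheritParams resolve_dc
#' @param rho Numeric density vector aligned to `distances`.
#' @return List with numeric `delta` and integer `nearest_higher`
#'   (`NA` for the global density maximum).
#' @export
compute_delta <- function(distances, rho) {
  distances <- check_distance_matrix(distances)
  n <- nrow(distances)
  if (length(rho) != n)
    stop("rho length does not match the distance matrix", call. = FALSE)
  # strict total order: rho descending, index ascending
  ord <- order(-rho, seq_len(n))
  rank_of <- integer(n)
  rank_of[ord] <- seq_len(n)
  delta <- numeric(n)
  nearest <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    higher <- which(rank_of < rank_of[i])
    if (!length(higher)) {             # global density maximum
      delta[i] <- max(distances[i, -i])
    } else {
      d <- distances[i, higher]
      j <- which(d == min(d))
      pick <- higher[j][which.min(higher[j])]  # tie -> lowest index
      delta[i] <- min(d)
      nearest[i] <- pick
    }
  }
  list(delta = delta, nearest_higher = nearest)
}

minmax <- function(x) {
  r <- range(x)
  if (r[2] - r[1] <= 0) return(rep(1, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

# gamma ranking: the global density maximum's delta is, by convention,
# its largest pairwise distance, which overstates its separation relative
# to every other peak; cap it at the largest delta among the remaining
# points before normalizing so the ranking reflects genuine structure.
dp_gamma <- function(rho, delta) {
  n <- length(rho)
  if (n > 1L) {
    top <- order(-rho, seq_len(n))[1]
    delta[top] <- min(delta[top], max(delta[-top]))
  }
  minmax(rho) * minmax(delta)
}

#' Select prototypes from the decision graph
#'
#' Prototypes are the points where the separation `delta` is anomalously
#' large for their density.  `gamma = rho~ * delta~` (both min-max
#' normalized to \[0, 1\]) ranks candidates; before normalizing, the
#' global density maximum's `delta` — by convention its largest pairwise
#' distance — is capped at the largest `delta` of the remaining points so
#' its `gamma` is not artificially inflated.  The configured rule then
#' cuts the ranking.  At least one prototype (the `gamma` maximum) is
#' always returned.
#'
#' @param rho,delta Numeric vectors of equal length (n >= 2).
#' @param config A [clustering_config].
#' @return Integer vector of prototype indices, sorted by descending
#'   `gamma` (ties by ascending index).
#' @export
select_prototypes <- function(rho, delta, config = clustering_config()) {
  n <- length(rho)
  if (length(delta) != n || n < 2L)
    stop("rho and delta must have equal length n >= 2", call. = FALSE)
  gamma <- dp_gamma(rho, delta)
  ord <- order(-gamma, seq_len(n))
  g <- gamma[ord]
  k <- switch(config$selection,
    fixed_k = {
      if (config$k > n)
        stop("fixed_k: k = ", config$k, " exceeds n = ", n, call. = FALSE)
      config$k
    },
    threshold = {
      keep <- gamma > mean(gamma) +
        config$threshold_multiplier * stats::sd(gamma)
      max(1L, sum(keep))
    },
    gamma_gap = {
      m <- min(n, ceiling(sqrt(n)))
      if (m < 2L) 1L else {
        top <- g[seq_len(m)]
        denom <- pmax(top[-1], .Machine$double.xmin)
        ratio <- top[-m] / denom
        which.max(ratio)               # cut after largest consecutive gap
      }
    })
  ord[seq_len(k)]
}

#' Density-peak clustering of a signature matrix
#'
#' Full pipeline: Euclidean distances, local density `rho`, separation
#' `delta`, prototype selection, and cluster labels.  By default every
#' point is labelled with its nearest prototype in the original space
#' (distance ties go to the higher-`gamma` prototype); `assign = "chain"`
#' instead inherits each point's label from its nearest higher-density
#' neighbour in density order.  Deterministic given data and config.
#'
#' @param x Numeric matrix (points x dimensions), or a [cohort].
#' @param config A [clustering_config].
#' @param timepoint Optional timepoint when `x` is a cohort.
#' @return An object of class `dp_result` with elements `rho`, `delta`,
#'   `nearest_higher`, `gamma`, `prototypes` (point indices), `labels`
#'   (1..K, cluster k anchored by the k-th prototype), `centroids`
#'   (prototype coordinates), `dc`, and `config`.
#' @export
dp_cluster <- function(x, config = clustering_config(), timepoint = NULL) {
  if (inherits(x, "cohort")) x <- signature_matrix(x, timepoint)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!all(is.finite(x)))
    stop("signature matrix contains non-finite values", call. = FALSE)
  n <- nrow(x)
  if (n < 2L) stop("clustering needs at least 2 points", call. = FALSE)
  distances <- as.matrix(stats::dist(x))
  dimnames(distances) <- NULL
  rho <- compute_rho(distances, config)
  ds <- compute_delta(distances, rho)
  prototypes <- select_prototypes(rho, ds$delta, config)
  gamma <- dp_gamma(rho, ds$delta)
  k <- length(prototypes)
  if (config$assign == "nearest") {
    pd <- distances[, prototypes, drop = FALSE]
    labels <- max.col(-pd, ties.method = "first")
  } else {
    labels <- integer(n)
    labels[prototypes] <- seq_len(k)
    ord <- order(-rho, seq_len(n))     # descending density order
    for (i in ord) {
      if (labels[i] == 0L) {
        nh <- ds$nearest_higher[i]
        if (is.na(nh)) {               # unselected global density maximum
          labels[i] <- which.min(distances[i, prototypes])
        } else {
          labels[i] <- labels[nh]
        }
      }
    }
  }
  structure(list(rho = rho, delta = ds$delta,
                 nearest_higher = ds$nearest_higher, gamma = gamma,
                 prototypes = prototypes, labels = labels,
                 centroids = x[prototypes, , drop = FALSE],
                 dc = resolve_dc(distances, config), config = config),
            class = "dp_result")
}

#' @export
print.dp_result <- function(x, ...) {
  cat("<dp_result> ", length(x$labels), " points, ",
      length(x$prototypes), " prototype(s) [selection: ",
      x$config$selection, ", kernel: ", x$config$kernel,
      ", d_c = ", signif(x$dc, 4), "]\n", sep = "")
  cat("cluster sizes:",
      paste(tabulate(x$labels, nbins = length(x$prototypes)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two label vectors; 1 means identical
#' partitions, ~0 means chance-level agreement.  Used by the planted-truth
#' recovery tests.
#'
#' @param a,b Label vectors of equal length (any atomic type).
#' @return Scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b))
    stop("label vectors must have equal length", call. = FALSE)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)     # both partitions trivial
  (sum_ij - expected) / (maxi - expected)
}
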