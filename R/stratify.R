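#' A set of labelled prototypes (class centroids)
#'
#' Prototypes anchor stratification: each class is represented by a
#' centroid in signature space, optionally weighted by a prior prevalence.
#'
#' @param centroids Numeric matrix, one row per prototype.
#' @param labels Character vector of unique class labels, one per row of
#'   `centroids` (defaults to row names, else `"C1"`, `"C2"`, ...).
#' @param priors Optional non-negative numeric vector summing to 1 over
#'   the labels.
#' @return An object of class `prototype_set`.
#' @export
prototype_set <- function(centroids, labels = NULL, priors = NULL) {
  centroids <- as.matrix(centroids)
  storage.mode(centroids) <- "double"
  k <- nrow(centroids)
  if (k < 1L) stop("need at least one prototype", call. = FALSE)
  if (is.null(labels)) labels <- rownames(centroids)
  if (is.null(labels)) labels <- paste0("C", seq_len(k))
  labels <- as.character(labels)
  if (length(labels) != k || anyDuplicated(labels))
    stop("labels must be unique, one per centroid", call. = FALSE)
  if (!is.null(priors)) {
    priors <- as.numeric(priors)
    if (length(priors) != k || any(priors < 0) ||
        abs(sum(priors) - 1) > 1e-9)
      stop("priors must be non-negative and sum to 1", call. = FALSE)
  }
  rownames(centroids) <- labels
  structure(list(labels = labels, centroids = centroids, priors = priors),
            class = "prototype_set")
}

#' @export
print.prototype_set <- function(x, ...) {
  cat("<prototype_set> ", length(x$labels), " prototype(s) in ",
      ncol(x$centroids), " dimension(s): ",
      paste(x$labels, collapse = ", "),
      if (!is.null(x$priors)) " (with priors)", "\n", sep = "")
  invisible(x)
}

#' Prototypes discovered by density-peak clustering
#'
#' Convenience bridge: wraps the prototype coordinates of a [dp_cluster]
#' result as a [prototype_set] whose labels are the cluster numbers.
#'
#' @param dp A `dp_result`.
#' @param priors Optional priors; `"empirical"` uses the observed cluster
#'   proportions.
#' @return A [prototype_set].
#' @export
prototypes_from_dp <- function(dp, priors = NULL) {
  stopifnot(inherits(dp, "dp_result"))
  labs <- as.character(seq_along(dp$prototypes))
  if (identical(priors, "empirical"))
    priors <- as.numeric(tabulate(dp$labels,
                                  nbins = length(dp$prototypes))) /
      length(dp$labels)
  prototype_set(dp$centroids, labs, priors)
}

#' Probabilistic class membership of signatures
#'
#' A membership is a row-stochastic matrix: one row per signature, one
#' column per class label, rows summing to 1.
#'
#' @param probabilities Numeric matrix (or vector for one signature).
#' @param labels Class labels, one per column.
#' @return An object of class `membership` (a matrix with a `labels`
#'   column naming).
#' @export
membership <- function(probabilities, labels = NULL) {
  p <- if (is.matrix(probabilities)) probabilities else
    matrix(probabilities, nrow = 1L)
  storage.mode(p) <- "double"
  if (is.null(labels)) labels <- colnames(p)
  if (is.null(labels))
    stop("membership needs class labels", call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != ncol(p) || anyDuplicated(labels))
    stop("labels must be unique, one per column", call. = FALSE)
  if (any(p < 0))
    stop("membership probabilities must be non-negative", call. = FALSE)
  if (any(abs(rowSums(p) - 1) > 1e-9))
    stop("membership rows must sum to 1", call. = FALSE)
  colnames(p) <- labels
  structure(p, class = c("membership", "matrix", "array"))
}

#' @export
print.membership <- function(x, ...) {
  cat("<membership> ", nrow(x), " signature(s) over classes: ",
      paste(colnames(x), collapse = ", "), "\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

distances_to_prototypes <- function(x, prototypes) {
  x <- if (is.matrix(x)) x else matrix(as.numeric(x), nrow = 1L)
  d <- ncol(prototypes$centroids)
  if (ncol(x) != d)
    stop("signature dimension ", ncol(x),
         " does not match prototype dimension ", d, call. = FALSE)
  # n x k matrix of Euclidean distances
  cross <- x %*% t(prototypes$centroids)
  sq <- outer(rowSums(x^2), rowSums(prototypes$centroids^2), "+") -
    2 * cross
  sqrt(pmax(sq, 0))
}

#' Hard assignment to the nearest prototype
#'
#' @param x Numeric vector (one signature) or matrix (one per row).
#' @param prototypes A [prototype_set].
#' @return Character vector of class labels; exact distance ties go to
#'   the earlier label in the prototype set's label order.
#' @export
hard_assign <- function(x, prototypes) {
  stopifnot(inherits(prototypes, "prototype_set"))
  d <- distances_to_prototypes(x, prototypes)
  prototypes$labels[max.col(-d, ties.method = "first")]
}

#' Soft (probabilistic) assignment to prototypes
#'
#' The likelihood of belonging to a class is a decreasing function of the
#' distance to its prototype.  The default Gaussian kernel gives
#' `P(k) proportional to exp(-d_k^2 / (2 * temperature^2))`: its argmax
#' always agrees with [hard_assign], it collapses to one-hot as
#' `temperature -> 0`, and flattens to uniform as `temperature -> Inf`.
#' The `"inverse"` kernel (`1 / (d_k + epsilon)`) is offered as a
#' heavier-tailed alternative.
#'
#' @inheritParams hard_assign
#' @param temperature Positive length scale of the Gaussian kernel.
#' @param kernel `"gaussian"` (default) or `"inverse"`.
#' @return A [membership] with one row per signature.
#' @export
soft_assign <- function(x, prototypes, temperature = 1,
                        kernel = c("gaussian", "inverse")) {
  kernel <- match.arg(kernel)
  stopifnot(inherits(prototypes, "prototype_set"))
  if (!(is.numeric(temperature) && length(temperature) == 1L &&
        temperature > 0))
    stop("temperature must be a positive scalar", call. = FALSE)
  d <- distances_to_prototypes(x, prototypes)
  if (kernel == "gaussian") {
    e <- -d^2 / (2 * temperature^2)
    e <- e - apply(e, 1L, max)         # log-sum-exp stabilisation
    w <- exp(e)
  } else {
    w <- 1 / (d + 1e-12)
  }
  membership(w / rowSums(w), prototypes$labels)
}

#' Weight a membership by class priors
#'
#' Bayes product: `posterior_k` proportional to `membership_k * prior_k`,
#' renormalized per signature.  A uniform prior is the identity.
#'
#' @param m A [membership].
#' @param priors Non-negative numeric vector over the membership's labels
#'   (summing to 1), or a [prototype_set] carrying priors.
#' @return A [membership] of posteriors.
#' @export
apply_prior <- function(m, priors) {
  stopifnot(inherits(m, "membership"))
  if (inherits(priors, "prototype_set")) {
    if (is.null(priors$priors))
      stop("prototype set carries no priors", call. = FALSE)
    priors <- priors$priors
  }
  priors <- as.numeric(priors)
  if (length(priors) != ncol(m) || any(priors < 0) ||
      abs(sum(priors) - 1) > 1e-9)
    stop("priors must be non-negative over the membership labels and sum",
         " to 1", call. = FALSE)
  post <- sweep(unclass(m), 2L, priors, "*")
  z <- rowSums(post)
  if (any(z <= 0))
    stop("degenerate evidence: prior and membership have disjoint support",
         call. = FALSE)
  membership(post / z, colnames(m))
}

#' Fit a two-class Fisher linear discriminant
#'
#' Closed-form Fisher LDA: `weights` proportional to
#' `pooled_covariance^-1 (mean_pos - mean_neg)`, with the offset placing
#' the decision boundary at the midpoint of the projected class means
#' (equal-prior rule).  When the pooled within-class covariance is
#' (near-)singular it is ridge-regularized by `1e-6 * trace / d` on the
#' diagonal.
#'
#' @param x Numeric matrix of training signatures (n x d, n >= 4).
#' @param labels Two-class label vector aligned to rows of `x`.
#' @param positive_label Which class maps to positive decision scores
#'   (default: first label in first-appearance order).
#' @return An object of class `linear_discriminant` with `weights`,
#'   `offset`, `positive_label`, `negative_label`.
#' @export
fit_discriminant <- function(x, labels, positive_label = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  labels <- as.character(labels)
  if (nrow(x) != length(labels))
    stop("labels must align with rows of x", call. = FALSE)
  classes <- unique(labels)
  if (length(classes) != 2L)
    stop("exactly two classes are required, got ", length(classes),
         call. = FALSE)
  if (is.null(positive_label)) positive_label <- classes[1]
  if (!positive_label %in% classes)
    stop("positive_label not among the supplied labels", call. = FALSE)
  negative_label <- setdiff(classes, positive_label)
  if (nrow(x) < 4L || min(table(labels)) < 2L)
    stop("need >= 2 points in each class (n >= 4)", call. = FALSE)
  xp <- x[labels == positive_label, , drop = FALSE]
  xn <- x[labels == negative_label, , drop = FALSE]
  mp <- colMeans(xp); mn <- colMeans(xn)
  sw <- (crossprod(sweep(xp, 2L, mp)) + crossprod(sweep(xn, 2L, mn))) /
    (nrow(x) - 2L)
  d <- ncol(x)
  w <- tryCatch(solve(sw, mp - mn), error = function(e) NULL)
  if (is.null(w) || rcond(sw) < 1e-12) {
    sw <- sw + diag(1e-6 * sum(diag(sw)) / d, d)
    w <- solve(sw, mp - mn)
  }
  if (all(w == 0))
    stop("degenerate discriminant: identical class means", call. = FALSE)
  offset <- -sum(w * (mp + mn)) / 2
  structure(list(weights = as.numeric(w), offset = offset,
                 positive_label = positive_label,
                 negative_label = negative_label),
            class = "linear_discriminant")
}

#' @export
print.linear_discriminant <- function(x, ...) {
  cat("<linear_discriminant> ", length(x$weights), "-dim; positive = '",
      x$positive_label, "', negative = '", x$negative_label, "'\n",
      sep = "")
  invisible(x)
}

#' Decision score of a linear discriminant
#'
#' @param x Signature vector or matrix (one per row).
#' @param discriminant A `linear_discriminant`.
#' @return Numeric vector `weights . x + offset`.
#' @export
discriminant_score <- function(x, discriminant) {
  stopifnot(inherits(discriminant, "linear_discriminant"))
  x <- if (is.matrix(x)) x else matrix(as.numeric(x), nrow = 1L)
  if (ncol(x) != length(discriminant$weights))
    stop("signature dimension does not match the discriminant",
         call. = FALSE)
  as.numeric(x %*% discriminant$weights + discriminant$offset)
}

#' Classify by which side of the discriminant a signature falls
#'
#' Positive score (including exactly zero, i.e. points on the boundary)
#' maps to the positive label.
#'
#' @inheritParams discriminant_score
#' @return Character vector of class labels.
#' @export
classify_side <- function(x, discriminant) {
  s <- discriminant_score(x, discriminant)
  ifelse(s >= 0, discriminant$positive_label, discriminant$negative_label)
}
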