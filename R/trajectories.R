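#' Estimate a cluster-transition model between two timepoints
#'
#' Clusters are estimated independently at each timepoint (baseline
#' clusters labelled e.g. A, B, C; follow-up clusters 1..5); the
#' trajectory model is then the conditional probability table (CPT)
#' `P(t2 cluster | t1 cluster)` estimated from patient-aligned
#' memberships.  `"hard"` counts each patient once in its argmax cell;
#' `"soft"` accumulates the fractional weight
#' `P(t1 = i) * P(t2 = j)` per patient (identical to hard counting when
#' memberships are one-hot).  Additive (Dirichlet) smoothing `alpha` is
#' applied per row; a zero-count row with `alpha = 0` falls back to a
#' uniform row with a warning.
#'
#' @param m1,m2 [membership] objects (or plain row-stochastic matrices
#'   with column labels) for the same patients, in the same row order, at
#'   time 1 and time 2.
#' @param mode `"hard"` or `"soft"` counting.
#' @param smoothing_alpha Non-negative additive smoothing pseudo-count.
#' @param patient_id Optional identifier vectors (length n each, or a
#'   list of two) used only to verify alignment.
#' @return An object of class `transition_model`: `t1_labels`,
#'   `t2_labels`, `cpt` (rows = t1, columns = t2, row-stochastic),
#'   `t1_marginal`, `counts`, `mode`, `smoothing_alpha`.
#' @export
estimate_transition <- function(m1, m2, mode = c("hard", "soft"),
                                smoothing_alpha = 0.5,
                                patient_id = NULL) {
  mode <- match.arg(mode)
  m1 <- as_membership(m1); m2 <- as_membership(m2)
  if (nrow(m1) != nrow(m2))
    stop("memberships cover different numbers of patients (",
         nrow(m1), " vs ", nrow(m2), ")", call. = FALSE)
  if (nrow(m1) < 1L) stop("need at least one patient", call. = FALSE)
  if (!is.null(patient_id)) {
    if (is.list(patient_id) && length(patient_id) == 2L &&
        !identical(as.character(patient_id[[1]]),
                   as.character(patient_id[[2]])))
      stop("patient identifiers are not aligned across timepoints",
           call. = FALSE)
  }
  if (!(is.numeric(smoothing_alpha) && length(smoothing_alpha) == 1L &&
        smoothing_alpha >= 0))
    stop("smoothing_alpha must be a non-negative scalar", call. = FALSE)
  t1_labels <- colnames(m1); t2_labels <- colnames(m2)
  if (mode == "hard") {
    i <- max.col(unclass(m1), ties.method = "first")
    j <- max.col(unclass(m2), ties.method = "first")
    counts <- matrix(0, length(t1_labels), length(t2_labels))
    for (p in seq_along(i)) counts[i[p], j[p]] <- counts[i[p], j[p]] + 1
  } else {
    counts <- crossprod(unclass(m1), unclass(m2))
  }
  dimnames(counts) <- list(t1_labels, t2_labels)
  row_tot <- rowSums(counts)
  denom <- row_tot + smoothing_alpha * length(t2_labels)
  cpt <- (counts + smoothing_alpha) / denom
  zero <- denom == 0
  if (any(zero)) {
    warning("transition row(s) with zero count and alpha = 0 set to ",
            "uniform: ", paste(t1_labels[zero], collapse = ", "),
            call. = FALSE)
    cpt[zero, ] <- 1 / length(t2_labels)
  }
  marginal <- if (sum(row_tot) > 0) row_tot / sum(row_tot) else
    rep(1 / length(t1_labels), length(t1_labels))
  names(marginal) <- t1_labels
  structure(list(t1_labels = t1_labels, t2_labels = t2_labels,
                 cpt = cpt, t1_marginal = marginal, counts = counts,
                 mode = mode, smoothing_alpha = smoothing_alpha),
            class = "transition_model")
}

as_membership <- function(m) {
  if (inherits(m, "membership")) return(m)
  membership(as.matrix(m), colnames(m))
}

#' @export
print.transition_model <- function(x, ...) {
  cat("<transition_model> ", length(x$t1_labels), " -> ",
      length(x$t2_labels), " clusters (", x$mode, " counts, alpha = ",
      x$smoothing_alpha, ")\n", sep = "")
  print(round(x$cpt, 3))
  invisible(x)
}

#' Predict time-2 cluster probabilities from soft time-1 evidence
#'
#' Soft-evidence marginalization over the transition CPT:
#' `P(t2 = j) = sum_i P(t1 = i) * cpt[i, j]`.  One-hot evidence returns
#' the corresponding CPT row exactly; the map is linear in the evidence.
#'
#' @param object A `transition_model`.
#' @param membership_t1 A [membership] (rows are patients) or a single
#'   probability vector over `object$t1_labels`.
#' @param ... Unused.
#' @return A [membership] over `object$t2_labels`.
#' @export
predict.transition_model <- function(object, membership_t1, ...) {
  m <- as_membership(
    if (is.matrix(membership_t1) || inherits(membership_t1, "membership"))
      membership_t1
    else matrix(membership_t1, nrow = 1L,
                dimnames = list(NULL, object$t1_labels)))
  if (!identical(colnames(m), object$t1_labels))
    stop("evidence labels do not match the model's time-1 labels",
         call. = FALSE)
  membership(unclass(m) %*% object$cpt, object$t2_labels)
}

#' Export a transition model as a weighted edge list
#'
#' One edge per CPT entry with probability `>= min_weight`, sorted by
#' time-1 label (model order) then descending probability — the tabular
#' form of the trajectory graph whose line weights encode transition
#' probability.
#'
#' @param model A `transition_model`.
#' @param min_weight Minimum probability in \[0, 1\] for an edge to be
#'   kept.
#' @return data.frame with columns `t1`, `t2`, `probability`.
#' @export
trajectory_graph <- function(model, min_weight = 0) {
  stopifnot(inherits(model, "transition_model"))
  if (!(is.numeric(min_weight) && length(min_weight) == 1L &&
        min_weight >= 0 && min_weight <= 1))
    stop("min_weight must lie in [0, 1]", call. = FALSE)
  df <- data.frame(
    t1 = rep(model$t1_labels, times = length(model$t2_labels)),
    t2 = rep(model$t2_labels, each = length(model$t1_labels)),
    probability = as.vector(model$cpt))
  df <- df[df$probability >= min_weight, , drop = FALSE]
  df <- df[order(match(df$t1, model$t1_labels), -df$probability), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read or write a transition model as JSON
#'
#' @param model A `transition_model`.
#' @param path File path.
#' @return `write_transition_model` returns `path` invisibly;
#'   `read_transition_model` returns a `transition_model`.
#' @export
write_transition_model <- function(model, path) {
  stopifnot(inherits(model, "transition_model"))
  jsonlite::write_json(
    list(t1_labels = model$t1_labels, t2_labels = model$t2_labels,
         cpt = model$cpt, t1_marginal = as.numeric(model$t1_marginal),
         counts = model$counts, mode = model$mode,
         smoothing_alpha = model$smoothing_alpha),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_transition_model
#' @export
read_transition_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  dn <- list(x$t1_labels, x$t2_labels)
  cpt <- matrix(as.numeric(t(x$cpt)), nrow = length(x$t1_labels),
                byrow = TRUE, dimnames = dn)
  counts <- matrix(as.numeric(t(x$counts)), nrow = length(x$t1_labels),
                   byrow = TRUE, dimnames = dn)
  structure(list(t1_labels = x$t1_labels, t2_labels = x$t2_labels,
                 cpt = cpt,
                 t1_marginal = stats::setNames(x$t1_marginal,
                                               x$t1_labels),
                 counts = counts, mode = x$mode,
                 smoothing_alpha = x$smoothing_alpha),
            class = "transition_model")
}
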