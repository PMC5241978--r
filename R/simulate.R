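#' Truncated-normal draws (inverse-CDF)
#'
#' @noRd
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(pmin(pmax(rep(mean, n), lo), hi))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  if (phi - plo <= 0)
    stop("degenerate truncation bounds [", lo, ", ", hi, "]",
         call. = FALSE)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Specification of the bimodal treatment-response simulation
#'
#' Emulates a two-axis (positive total, negative total) cohort exposed to
#' a hypothetical intervention that improves *only* the positive-symptom
#' score, by a fixed proportion, in only a fraction of patients: 100
#' patients, 50% responders, 80% positive-symptom improvement by default.
#' Baseline totals are truncated normal per axis; the defaults use
#' symptom-load coding (each of 7 subscale items scored 0-6, so totals
#' span 0-42) with mean 22 and SD 6.
#'
#' @param n_patients Number of patients (default 100).
#' @param responder_fraction Probability a patient responds (default
#'   0.5).
#' @param positive_improvement Proportional reduction of the responder's
#'   positive score at follow-up (default 0.8, i.e. t2 = 0.2 * t1 plus
#'   noise).
#' @param baseline_positive_mean,baseline_positive_sd Baseline truncated
#'   normal for the positive axis (defaults 22, 6).
#' @param baseline_negative_mean,baseline_negative_sd Same for the
#'   negative axis.
#' @param followup_noise_sd SD of additive follow-up noise on both axes
#'   (default 2 score points).
#' @param bounds Length-2 numeric `c(min, max)` applied to both axes
#'   (default `c(0, 42)`); generated values are clipped to the bounds.
#' @param seed Optional integer seed; the draw is fully reproducible.
#' @return An object of class `bimodal_response_spec`.
#' @export
bimodal_response_spec <- function(n_patients = 100,
                                  responder_fraction = 0.5,
                                  positive_improvement = 0.8,
                                  baseline_positive_mean = 22,
                                  baseline_positive_sd = 6,
                                  baseline_negative_mean = 22,
                                  baseline_negative_sd = 6,
                                  followup_noise_sd = 2,
                                  bounds = c(0, 42),
                                  seed = NULL) {
  stopifnot(n_patients >= 1, n_patients == round(n_patients),
            responder_fraction >= 0, responder_fraction <= 1,
            positive_improvement >= 0, positive_improvement <= 1,
            baseline_positive_sd >= 0, baseline_negative_sd >= 0,
            followup_noise_sd >= 0)
  bounds <- as.numeric(bounds)
  if (length(bounds) != 2L || bounds[1] >= bounds[2])
    stop("bounds must be c(min, max) with min < max", call. = FALSE)
  structure(as.list(environment()), class = "bimodal_response_spec")
}

#' Simulate a bimodal treatment response (two axes, two timepoints)
#'
#' Each patient is independently a responder with probability
#' `responder_fraction`.  At follow-up a responder's positive score is
#' `(1 - positive_improvement) * baseline + noise`; the negative score,
#' and both scores of non-responders, change by noise only.  All values
#' are clipped to the declared bounds.  In aggregate (summed) scores the
#' effect is diluted; in the two-dimensional signature space the
#' responders separate as a distinct follow-up cluster.
#'
#' @param spec A [bimodal_response_spec].
#' @return List with `cohort` (a two-timepoint [cohort] on axes
#'   `positive_total`, `negative_total`), and `responder` (logical
#'   planted truth, one per patient).
#' @export
simulate_bimodal_response <- function(spec = bimodal_response_spec()) {
  stopifnot(inherits(spec, "bimodal_response_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_patients
  lo <- spec$bounds[1]; hi <- spec$bounds[2]
  pos1 <- rtruncnorm(n, spec$baseline_positive_mean,
                     spec$baseline_positive_sd, lo, hi)
  neg1 <- rtruncnorm(n, spec$baseline_negative_mean,
                     spec$baseline_negative_sd, lo, hi)
  responder <- stats::runif(n) < spec$responder_fraction
  clip <- function(x) pmin(pmax(x, lo), hi)
  noise <- function() stats::rnorm(n, 0, spec$followup_noise_sd)
  pos2 <- clip(ifelse(responder,
                      (1 - spec$positive_improvement) * pos1,
                      pos1) + noise())
  neg2 <- clip(neg1 + noise())
  sc <- scale_definition("panss_domain_totals",
                         c("positive_total", "negative_total"),
                         item_range = spec$bounds)
  ids <- sprintf("P%03d", seq_len(n))
  vals <- rbind(cbind(pos1, neg1), cbind(pos2, neg2))
  dimnames(vals) <- NULL
  co <- cohort(sc, rep(ids, 2), rep(c("t1", "t2"), each = n), vals)
  list(cohort = co, responder = responder, spec = spec)
}

#' Specification of a planted Gaussian-mixture cohort
#'
#' Isotropic Gaussian clusters with centroids placed (after a seeded
#' random draw of directions) so that the minimum pairwise centroid
#' distance equals `separation * within_sd` — "separation 8" therefore
#' means the closest pair of centroids is 8 within-cluster SDs apart.
#'
#' @param n_points,n_dims,n_clusters Cohort size, dimensionality and
#'   number of planted clusters.
#' @param separation Minimum centroid spacing in units of `within_sd`.
#' @param within_sd Within-cluster (isotropic) SD.
#' @param weights Mixture weights (default uniform), summing to 1.
#' @param bounds Optional `c(min, max)` clipping per coordinate.
#' @param seed Optional integer seed.
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(n_points, n_dims, n_clusters, separation = 8,
                         within_sd = 1, weights = NULL, bounds = NULL,
                         seed = NULL) {
  stopifnot(n_points >= 1, n_dims >= 1, n_clusters >= 1,
            separation > 0, within_sd > 0)
  if (is.null(weights)) weights <- rep(1 / n_clusters, n_clusters)
  weights <- as.numeric(weights)
  if (length(weights) != n_clusters || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9)
    stop("weights must be a length-n_clusters probability vector",
         call. = FALSE)
  if (!is.null(bounds)) {
    bounds <- as.numeric(bounds)
    if (length(bounds) != 2L || bounds[1] >= bounds[2])
      stop("bounds must be c(min, max) with min < max", call. = FALSE)
  }
  structure(as.list(environment()), class = "mixture_spec")
}

place_centroids <- function(k, d, min_dist) {
  if (k == 1L) return(matrix(0, 1L, d))
  if (k > 1L && d == 1L && k > 2L && min_dist <= 0)
    stop("impossible packing", call. = FALSE)
  raw <- matrix(stats::rnorm(k * d), k, d)
  dm <- as.matrix(stats::dist(raw))
  m <- min(dm[lower.tri(dm)])
  if (m <= 0)
    stop("impossible packing: coincident centroid draws", call. = FALSE)
  raw * (min_dist / m)
}

#' Simulate a planted Gaussian-mixture cohort
#'
#' @param spec A [mixture_spec].
#' @param timepoint Timepoint label recorded on the cohort (default
#'   `"t1"`).
#' @return List with `cohort` (single-timepoint [cohort] on generic axes
#'   `dim1..dimd`), `labels` (planted integer labels) and `centroids`.
#' @export
simulate_mixture <- function(spec, timepoint = "t1") {
  stopifnot(inherits(spec, "mixture_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  centroids <- place_centroids(spec$n_clusters, spec$n_dims,
                               spec$separation * spec$within_sd)
  labels <- sample.int(spec$n_clusters, spec$n_points, replace = TRUE,
                       prob = spec$weights)
  pts <- centroids[labels, , drop = FALSE] +
    matrix(stats::rnorm(spec$n_points * spec$n_dims, 0, spec$within_sd),
           spec$n_points, spec$n_dims)
  if (!is.null(spec$bounds))
    pts <- pmin(pmax(pts, spec$bounds[1]), spec$bounds[2])
  sc <- scale_definition("synthetic_mixture",
                         paste0("dim", seq_len(spec$n_dims)),
                         item_range = spec$bounds)
  ids <- sprintf("P%04d", seq_len(spec$n_points))
  list(cohort = cohort(sc, ids, timepoint, pts),
       labels = labels, centroids = centroids, spec = spec)
}

#' Specification of a two-timepoint transition cohort
#'
#' Baseline signatures come from a planted mixture; each patient's
#' follow-up cluster is drawn from the transition row of its true
#' baseline cluster, and its follow-up signature from an isotropic
#' Gaussian around the corresponding follow-up centroid.  This is the
#' planted-truth world for conditional-probability-table recovery (e.g.
#' 3 baseline clusters flowing into 5 follow-up clusters).
#'
#' @param t1_mixture A [mixture_spec] for the baseline.
#' @param transition Row-stochastic matrix, one row per baseline cluster,
#'   one column per follow-up cluster.
#' @param t2_centroids Matrix of follow-up centroids (rows = follow-up
#'   clusters, same dimension as the baseline mixture); `NULL` places
#'   them like a fresh mixture draw at the baseline separation.
#' @param t2_within_sd Within-cluster SD at follow-up.
#' @param seed Optional integer seed.
#' @return An object of class `two_timepoint_spec`.
#' @export
two_timepoint_spec <- function(t1_mixture, transition,
                               t2_centroids = NULL, t2_within_sd = 1,
                               seed = NULL) {
  stopifnot(inherits(t1_mixture, "mixture_spec"), t2_within_sd > 0)
  transition <- as.matrix(transition)
  if (nrow(transition) != t1_mixture$n_clusters)
    stop("transition must have one row per baseline cluster",
         call. = FALSE)
  if (any(transition < 0) ||
      any(abs(rowSums(transition) - 1) > 1e-9))
    stop("transition rows must be probability vectors", call. = FALSE)
  if (!is.null(t2_centroids)) {
    t2_centroids <- as.matrix(t2_centroids)
    if (nrow(t2_centroids) != ncol(transition))
      stop("t2_centroids count must equal transition columns",
           call. = FALSE)
    if (ncol(t2_centroids) != t1_mixture$n_dims)
      stop("t2_centroids dimension must match the baseline mixture",
           call. = FALSE)
  }
  structure(list(t1_mixture = t1_mixture, transition = transition,
                 t2_centroids = t2_centroids,
                 t2_within_sd = t2_within_sd, seed = seed),
            class = "two_timepoint_spec")
}

#' Simulate a two-timepoint transition cohort
#'
#' @param spec A [two_timepoint_spec].
#' @return List with `cohort` (both timepoints, aligned patient ids),
#'   `labels_t1`, `labels_t2` (planted truth), `t1_centroids`,
#'   `t2_centroids`.
#' @export
simulate_two_timepoint <- function(spec) {
  stopifnot(inherits(spec, "two_timepoint_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  mix <- spec$t1_mixture
  mix$seed <- NULL                     # one seed governs the whole draw
  t1 <- simulate_mixture(mix)
  k2 <- ncol(spec$transition)
  t2c <- spec$t2_centroids
  if (is.null(t2c))
    t2c <- place_centroids(k2, mix$n_dims,
                           mix$separation * spec$t2_within_sd)
  n <- mix$n_points
  labels_t2 <- integer(n)
  for (i in seq_len(n))
    labels_t2[i] <- sample.int(k2, 1L,
                               prob = spec$transition[t1$labels[i], ])
  pts2 <- t2c[labels_t2, , drop = FALSE] +
    matrix(stats::rnorm(n * mix$n_dims, 0, spec$t2_within_sd),
           n, mix$n_dims)
  if (!is.null(mix$bounds))
    pts2 <- pmin(pmax(pts2, mix$bounds[1]), mix$bounds[2])
  co <- cohort(t1$cohort$scale,
               c(t1$cohort$patient_id, t1$cohort$patient_id),
               rep(c("t1", "t2"), each = n),
               rbind(t1$cohort$values, pts2))
  list(cohort = co, labels_t1 = t1$labels, labels_t2 = labels_t2,
       t1_centroids = t1$centroids, t2_centroids = t2c, spec = spec)
}
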