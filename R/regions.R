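#' Outcome regions in signature space
#'
#' A multivariate outcome is a *region* of signature space: a trajectory
#' endpoint falling inside the region counts as treatment success.  Three
#' region kinds are supported, all closed (boundary points are inside):
#' a ball of given radius around a prototype, one side of a fitted linear
#' discriminant, and a finite union of regions.
#'
#' @param center Numeric centre of the ball.
#' @param radius Positive radius.
#' @return An object of class `region`.
#' @examples
#' b <- region_ball(c(0, 0), 2)
#' region_contains(b, c(2, 0))   # boundary -> TRUE
#' @export
region_ball <- function(center, radius) {
  center <- as.numeric(center)
  if (!(is.numeric(radius) && length(radius) == 1L && radius > 0))
    stop("radius must be a positive scalar", call. = FALSE)
  structure(list(kind = "ball", center = center, radius = radius,
                 dim = length(center)),
            class = "region")
}

#' @rdname region_ball
#' @param discriminant A `linear_discriminant` (see [fit_discriminant]).
#' @param side Which side counts as inside: `"positive"` or
#'   `"negative"` decision scores.
#' @export
region_halfspace <- function(discriminant, side = c("positive",
                                                    "negative")) {
  side <- match.arg(side)
  stopifnot(inherits(discriminant, "linear_discriminant"))
  structure(list(kind = "halfspace", discriminant = discriminant,
                 side = side, dim = length(discriminant$weights)),
            class = "region")
}

#' @rdname region_ball
#' @param ... For `region_union`: two or more `region` objects of the
#'   same dimension (a single list is also accepted).
#' @export
region_union <- function(...) {
  members <- list(...)
  if (length(members) == 1L && is.list(members[[1]]) &&
      !inherits(members[[1]], "region"))
    members <- members[[1]]
  if (!length(members))
    stop("a union region needs at least one member", call. = FALSE)
  if (!all(vapply(members, inherits, logical(1), "region")))
    stop("all union members must be regions", call. = FALSE)
  dims <- vapply(members, `[[`, numeric(1), "dim")
  if (length(unique(dims)) != 1L)
    stop("union members have inconsistent dimensions", call. = FALSE)
  structure(list(kind = "union", members = members, dim = dims[1]),
            class = "region")
}

#' @export
print.region <- function(x, ...) {
  desc <- switch(x$kind,
    ball = paste0("ball(r = ", signif(x$radius, 4), ")"),
    halfspace = paste0("halfspace(", x$side, " side)"),
    union = paste0("union of ", length(x$members)))
  cat("<region> ", desc, " in ", x$dim, " dimension(s)\n", sep = "")
  invisible(x)
}

#' Test whether signatures fall inside a region
#'
#' Regions are closed: a point at exactly the ball radius, or exactly on
#' the discriminant boundary of the positive side, is inside.
#'
#' @param region A `region`.
#' @param x Signature vector or matrix (one signature per row).
#' @return Logical vector, one entry per signature.
#' @export
region_contains <- function(region, x) {
  stopifnot(inherits(region, "region"))
  x <- if (is.matrix(x)) x else matrix(as.numeric(x), nrow = 1L)
  if (ncol(x) != region$dim)
    stop("signature dimension ", ncol(x),
         " does not match region dimension ", region$dim, call. = FALSE)
  switch(region$kind,
    ball = {
      d <- sqrt(rowSums(sweep(x, 2L, region$center)^2))
      d <= region$radius
    },
    halfspace = {
      lab <- classify_side(x, region$discriminant)
      tgt <- if (region$side == "positive")
        region$discriminant$positive_label else
        region$discriminant$negative_label
      lab == tgt
    },
    union = {
      inside <- rep(FALSE, nrow(x))
      for (m in region$members) inside <- inside | region_contains(m, x)
      inside
    })
}

#' Evaluate a cohort's response against an outcome region
#'
#' Applies [region_contains] to every follow-up signature and summarises
#' the crude multivariate response rate: the fraction of patients whose
#' endpoint lies inside the region.
#'
#' @param x A [cohort] (typically subset to the follow-up timepoint) or a
#'   signature matrix.
#' @param region A `region`.
#' @param timepoint Optional timepoint to subset a cohort to.
#' @return List with `responded` (named logical vector, keyed by
#'   patient id when available) and `response_rate` in \[0, 1\].
#' @export
evaluate_response <- function(x, region, timepoint = NULL) {
  ids <- NULL
  if (inherits(x, "cohort")) {
    if (!is.null(timepoint)) x <- cohort_at(x, timepoint)
    ids <- x$patient_id
    x <- x$values
  }
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("empty cohort", call. = FALSE)
  inside <- region_contains(region, x)
  if (!is.null(ids)) names(inside) <- ids
  list(responded = inside, response_rate = mean(inside))
}
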