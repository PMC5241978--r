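#' Construct a cohort of patient signatures
#'
#' A cohort binds a [scale_definition] to a set of signatures: one row per
#' (patient, timepoint), with the signature coordinates aligned to the
#' scale's item order.  Row order of the input is preserved and is the
#' canonical patient order used by all per-point outputs downstream
#' (density, separation, cluster labels).
#'
#' @param scale A [scale_definition].
#' @param patient_id Character vector of patient identifiers.
#' @param timepoint Character vector of timepoint labels (e.g. `"t1"`).
#' @param values Numeric matrix, one row per signature, columns aligned to
#'   `scale$items` (matched by column name when present).
#' @return An object of class `cohort`.
#' @export
cohort <- function(scale, patient_id, timepoint, values) {
  stopifnot(inherits(scale, "scale_definition"))
  patient_id <- as.character(patient_id)
  timepoint <- as.character(timepoint)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- length(patient_id)
  if (length(timepoint) == 1L) timepoint <- rep(timepoint, n)
  if (length(timepoint) != n || nrow(values) != n)
    stop("patient_id, timepoint and values rows must align", call. = FALSE)
  d <- length(scale$items)
  if (ncol(values) != d)
    stop("signature length ", ncol(values), " does not match the ", d,
         "-item scale '", scale$name, "'", call. = FALSE)
  if (!is.null(colnames(values))) {
    if (!setequal(colnames(values), scale$items))
      stop("value columns do not match scale items", call. = FALSE)
    values <- values[, scale$items, drop = FALSE]
  } else {
    colnames(values) <- scale$items
  }
  if (anyNA(values))
    stop("missing signature values are not allowed; first offender: patient ",
         patient_id[which(rowSums(is.na(values)) > 0)[1]], call. = FALSE)
  key <- paste(patient_id, timepoint, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (patient_id, timepoint) pair: ",
         sub("\r", " @ ", key[duplicated(key)][1]), call. = FALSE)
  if (!is.null(scale$item_range)) {
    lo <- scale$item_range[1]; hi <- scale$item_range[2]
    bad <- which(values < lo | values > hi, arr.ind = TRUE)
    if (nrow(bad))
      stop("value out of declared range [", lo, ", ", hi, "]: patient ",
           patient_id[bad[1, 1]], ", item ", scale$items[bad[1, 2]],
           " = ", values[bad[1, 1], bad[1, 2]], call. = FALSE)
  }
  rownames(values) <- NULL
  structure(list(scale = scale, patient_id = patient_id,
                 timepoint = timepoint, values = values),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", length(x$patient_id), " signatures x ",
      length(x$scale$items), " items (scale '", x$scale$name, "'); ",
      "timepoints: ", paste(unique(x$timepoint), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

n_signatures <- function(x) length(x$patient_id)

#' Extract the signature matrix of a cohort
#'
#' @param x A [cohort].
#' @param timepoint Optional timepoint label to subset to.
#' @return Numeric matrix (signatures x items), rows in canonical order.
#' @export
signature_matrix <- function(x, timepoint = NULL) {
  stopifnot(inherits(x, "cohort"))
  v <- x$values
  if (!is.null(timepoint)) v <- v[x$timepoint == timepoint, , drop = FALSE]
  v
}

#' Subset a cohort to one timepoint
#'
#' @inheritParams signature_matrix
#' @return A [cohort] containing only the requested timepoint.
#' @export
cohort_at <- function(x, timepoint) {
  stopifnot(inherits(x, "cohort"))
  keep <- x$timepoint == timepoint
  if (!any(keep))
    stop("no signatures at timepoint '", timepoint, "'", call. = FALSE)
  cohort(x$scale, x$patient_id[keep], x$timepoint[keep],
         x$values[keep, , drop = FALSE])
}

#' Load a cohort table from CSV
#'
#' Two layouts are accepted.  Wide: `patient_id, timepoint, <item1> ...
#' <itemd>`, one row per signature.  Long: `patient_id, timepoint, item,
#' value`, one row per item score.  Values are validated against the
#' scale's declared item range; missing values and duplicate
#' (patient, timepoint) pairs are errors, not warnings.  Row order (first
#' appearance, for long layout) is preserved as canonical order.
#'
#' @param path CSV file with a header row.
#' @param scale A [scale_definition].
#' @param layout `"wide"` or `"long"`.
#' @return A [cohort].
#' @export
load_cohort <- function(path, scale, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  stopifnot(inherits(scale, "scale_definition"))
  if (!file.exists(path))
    stop("cohort file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  for (col in c("patient_id", "timepoint"))
    if (!col %in% names(df))
      stop("cohort file lacks required column '", col, "'", call. = FALSE)
  if (layout == "wide") {
    missing <- setdiff(scale$items, names(df))
    if (length(missing))
      stop("cohort file lacks item column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    vals <- as.matrix(df[, scale$items, drop = FALSE])
    cohort(scale, df$patient_id, df$timepoint, vals)
  } else {
    for (col in c("item", "value"))
      if (!col %in% names(df))
        stop("long cohort file lacks required column '", col, "'",
             call. = FALSE)
    bad <- setdiff(unique(df$item), scale$items)
    if (length(bad))
      stop("long cohort file contains unknown item(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    key <- paste(df$patient_id, df$timepoint, sep = "\r")
    ord <- unique(key)  # first-appearance order
    idx <- match(key, ord)
    col <- match(df$item, scale$items)
    dup <- duplicated(cbind(idx, col))
    if (any(dup))
      stop("duplicate item entry for patient ",
           df$patient_id[dup][1], ", item ", df$item[dup][1],
           call. = FALSE)
    vals <- matrix(NA_real_, nrow = length(ord),
                   ncol = length(scale$items),
                   dimnames = list(NULL, scale$items))
    vals[cbind(idx, col)] <- as.numeric(df$value)
    if (anyNA(vals)) {
      miss <- which(is.na(vals), arr.ind = TRUE)[1, ]
      stop("long cohort file is missing item '",
           scale$items[miss[2]], "' for ",
           sub("\r", " @ ", ord[miss[1]]), call. = FALSE)
    }
    first <- !duplicated(key)
    cohort(scale, df$patient_id[first], df$timepoint[first], vals)
  }
}

#' Write a cohort to CSV
#'
#' @param x A [cohort].
#' @param path Output file.
#' @param layout `"wide"` or `"long"` (see [load_cohort]).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  stopifnot(inherits(x, "cohort"))
  if (layout == "wide") {
    df <- data.frame(patient_id = x$patient_id, timepoint = x$timepoint,
                     x$values, check.names = FALSE)
  } else {
    d <- ncol(x$values)
    df <- data.frame(
      patient_id = rep(x$patient_id, each = d),
      timepoint = rep(x$timepoint, each = d),
      item = rep(colnames(x$values), times = nrow(x$values)),
      value = as.vector(t(x$values)))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Euclidean distance between two signatures
#'
#' Patient similarity in a signature space is inversely proportional to the
#' straight-line (Euclidean) distance between the two points.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Non-negative scalar distance.
#' @export
euclidean_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b))
    stop("signature dimensions differ (", length(a), " vs ", length(b),
         ")", call. = FALSE)
  sqrt(sum((a - b)^2))
}

#' Aggregate (summed) domain scores for a cohort
#'
#' Collapses each signature to the univariate totals traditionally used as
#' composite outcomes: one summed score per declared scale domain.
#'
#' @param x A [cohort] whose scale declares at least one domain.
#' @return A data.frame with columns `patient_id`, `timepoint`, `domain`,
#'   `score`, one row per (signature, domain).
#' @export
aggregate_domain_scores <- function(x) {
  stopifnot(inherits(x, "cohort"))
  dom <- x$scale$domains
  if (is.null(dom) || !length(dom))
    stop("scale '", x$scale$name, "' declares no domains", call. = FALSE)
  out <- lapply(names(dom), function(dn) {
    data.frame(patient_id = x$patient_id, timepoint = x$timepoint,
               domain = dn,
               score = rowSums(x$values[, dom[[dn]], drop = FALSE]))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Standardize cohort signatures
#'
#' `"zscore"` centres each item at its cross-cohort mean and scales by its
#' population standard deviation (denominator n); zero-variance items are
#' centred but left unscaled (all zeros).  `"none"` is the identity.
#' Single-instrument ordinal scales sharing one range (e.g. PANSS 1-7) are
#' typically clustered raw; standardization matters when axes mix units,
#' because Euclidean distance is scale-sensitive.
#'
#' @param x A [cohort].
#' @param method `"none"` or `"zscore"`.
#' @return A [cohort] (for `"zscore"`, bounds no longer apply and the
#'   returned scale drops its `item_range`).
#' @export
standardize <- function(x, method = c("none", "zscore")) {
  method <- match.arg(method)
  stopifnot(inherits(x, "cohort"))
  if (method == "none") return(x)
  n <- nrow(x$values)
  if (n < 2L)
    stop("zscore standardization needs at least 2 signatures",
         call. = FALSE)
  mu <- colMeans(x$values)
  sd_pop <- sqrt(colMeans(sweep(x$values, 2L, mu)^2))
  ctr <- sweep(x$values, 2L, mu)
  nz <- sd_pop > 0
  ctr[, nz] <- sweep(ctr[, nz, drop = FALSE], 2L, sd_pop[nz], "/")
  sc <- x$scale
  sc$item_range <- NULL
  cohort(sc, x$patient_id, x$timepoint, ctr)
}
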