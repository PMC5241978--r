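#' Define a clinical scale (the axes of a signature space)
#'
#' A scale definition names the ordered items (dimensions) of a signature
#' space, optionally groups items into clinical domains (e.g. positive /
#' negative / general symptoms), and optionally declares per-item numeric
#' bounds used to validate cohort data on load.
#'
#' @param name Scale name, e.g. `"PANSS"`.
#' @param items Character vector of unique item labels; their order fixes
#'   the coordinate order of every signature on this scale.
#' @param domains Optional named list mapping a domain label to a character
#'   vector of item labels.  Domains must be non-empty, pairwise disjoint
#'   subsets of `items`.
#' @param item_range Optional numeric vector `c(min, max)` applied to every
#'   item, with `min < max`.
#' @return An object of class `scale_definition`.
#' @examples
#' sc <- scale_definition("toy", c("p1", "p2", "n1"),
#'                        domains = list(positive = c("p1", "p2"),
#'                                       negative = "n1"),
#'                        item_range = c(1, 7))
#' @export
scale_definition <- function(name, items, domains = NULL, item_range = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  items <- as.character(items)
  if (length(items) < 1L)
    stop("a scale needs at least one item", call. = FALSE)
  if (anyDuplicated(items))
    stop("scale item labels must be unique", call. = FALSE)
  if (!is.null(domains)) {
    if (is.null(names(domains)) || any(!nzchar(names(domains))) ||
        anyDuplicated(names(domains)))
      stop("domains must be a uniquely named list", call. = FALSE)
    seen <- character(0)
    for (dn in names(domains)) {
      dv <- as.character(domains[[dn]])
      if (length(dv) == 0L)
        stop("domain '", dn, "' is empty", call. = FALSE)
      bad <- setdiff(dv, items)
      if (length(bad))
        stop("domain '", dn, "' names unknown item(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
      if (length(intersect(dv, seen)))
        stop("domains must be pairwise disjoint; item(s) repeated: ",
             paste(intersect(dv, seen), collapse = ", "), call. = FALSE)
      seen <- c(seen, dv)
      domains[[dn]] <- dv
    }
  }
  if (!is.null(item_range)) {
    item_range <- as.numeric(item_range)
    if (length(item_range) != 2L || !all(is.finite(item_range)) ||
        item_range[1] >= item_range[2])
      stop("item_range must be c(min, max) with min < max", call. = FALSE)
  }
  structure(list(name = name, items = items, domains = domains,
                 item_range = item_range),
            class = "scale_definition")
}

#' @export
print.scale_definition <- function(x, ...) {
  cat("<scale_definition> ", x$name, ": ", length(x$items), " items",
      sep = "")
  if (!is.null(x$domains))
    cat("; domains: ",
        paste(sprintf("%s (%d)", names(x$domains),
                      lengths(x$domains)), collapse = ", "),
        sep = "")
  if (!is.null(x$item_range))
    cat("; range [", x$item_range[1], ", ", x$item_range[2], "]", sep = "")
  cat("\n")
  invisible(x)
}

#' The 30-item PANSS scale definition
#'
#' Positive and Negative Syndrome Scale: 7 positive, 7 negative and 16
#' general psychopathology items, each scored on an ordinal 1-7 severity
#' range.  Item labels follow the conventional P1-P7 / N1-N7 / G1-G16
#' codes.
#'
#' @return A [scale_definition] with 30 items and three domains.
#' @export
panss_scale <- function() {
  items <- c(paste0("P", 1:7), paste0("N", 1:7), paste0("G", 1:16))
  scale_definition(
    "PANSS", items,
    domains = list(positive = paste0("P", 1:7),
                   negative = paste0("N", 1:7),
                   general  = paste0("G", 1:16)),
    item_range = c(1, 7))
}

#' The five-domain neurocognitive Z-score scale
#'
#' Composite Z-scores over five neurocognitive domains: verbal working
#' memory, vigilance, speed of processing, reasoning, and memory.
#' Unbounded (Z-scores), no domain grouping beyond the items themselves.
#'
#' @return A [scale_definition] with 5 items.
#' @export
neurocognitive_scale <- function() {
  scale_definition(
    "neurocognitive",
    c("verbal_working_memory", "vigilance", "processing_speed",
      "reasoning", "memory"))
}

#' Read or write a scale definition as JSON
#'
#' @param path File path.
#' @return `read_scale` returns a [scale_definition]; `write_scale`
#'   returns `path` invisibly.
#' @export
read_scale <- function(path) {
  if (!file.exists(path))
    stop("scale file not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  scale_definition(x$name, x$items,
                   domains = if (length(x$domains)) as.list(x$domains),
                   item_range = x$item_range)
}

#' @rdname read_scale
#' @param scale A [scale_definition].
#' @export
write_scale <- function(scale, path) {
  stopifnot(inherits(scale, "scale_definition"))
  jsonlite::write_json(
    list(name = scale$name, items = scale$items,
         domains = scale$domains, item_range = scale$item_range),
    path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}
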