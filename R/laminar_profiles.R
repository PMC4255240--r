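# Regression-stump split of laminar depth profiles: one change point in the
# mean neuron count along a normalized 0-100 depth axis.

#' Construct a laminar depth profile
#'
#' Counts of labeled neurons per depth bin along a normalized axis (0 = top
#' of layer 4, 100 = bottom of layer 1, for supragranular profiles).
#'
#' @param depth strictly increasing bin centers in (0, 100).
#' @param count finite non-negative counts (or percentages) per bin.
#' @return data frame of class \code{depth_profile}.
#' @export
depth_profile <- function(depth, count) {
  stopifnot(length(depth) == length(count))
  if (is.unsorted(depth, strictly = TRUE))
    stop("depth bins must be strictly increasing")
  if (any(!is.finite(count)) || any(count < 0))
    stop("counts must be finite and non-negative")
  structure(data.frame(depth = depth, count = count),
            class = c("depth_profile", "data.frame"))
}

#' Read a depth profile from two-column delimited text
#'
#' Expects a header row with columns \code{DEPTH} and \code{COUNT}
#' (tab or comma separated, auto-detected).
#'
#' @param path file path.
#' @return a \code{\link{depth_profile}}.
#' @export
read_depth_profile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, fileEncoding = "UTF-8")
  names(raw) <- toupper(names(raw))
  if (!all(c("DEPTH", "COUNT") %in% names(raw)))
    stop("header must name DEPTH and COUNT")
  depth_profile(raw$DEPTH, raw$COUNT)
}

#' Single-split regression stump on a depth profile
#'
#' Exhaustive search over the midpoints between adjacent depth bins for the
#' split that minimizes the total squared deviation of the counts from their
#' two segment means -- the regression-tree criterion restricted to one
#' split of one variable.  Ties are broken toward the smallest threshold.
#' The compartment (\code{mean_inside}) is the segment with the larger mean
#' count.  A constant profile admits no split and is returned with
#' \code{split = FALSE}.
#'
#' @param profile a \code{\link{depth_profile}} with at least 4 bins.
#' @return list of class \code{depth_split}: \code{split} (logical),
#'   \code{threshold_depth}, \code{mean_below}/\code{mean_above} (segment
#'   means below/above the threshold), \code{mean_inside}/\code{mean_outside}
#'   (compartment vs rest), \code{rss} and \code{rss_null} (single-mean
#'   model).
#' @export
fit_depth_split <- function(profile) {
  stopifnot(inherits(profile, "depth_profile"))
  d <- profile$depth; y <- profile$count
  if (length(d) < 4) stop("need at least 4 depth bins")
  rss_null <- sum((y - mean(y))^2)
  if (rss_null == 0)
    return(structure(list(split = FALSE, threshold_depth = NA_real_,
                          mean_below = mean(y), mean_above = mean(y),
                          mean_inside = mean(y), mean_outside = mean(y),
                          rss = rss_null, rss_null = rss_null),
                     class = "depth_split"))
  cand <- (d[-1] + d[-length(d)]) / 2
  best <- NULL
  for (t in cand) {
    left <- y[d < t]; right <- y[d >= t]
    rss <- sum((left - mean(left))^2) + sum((right - mean(right))^2)
    if (is.null(best) || rss < best$rss - 1e-12)  # strict: first (smallest) wins ties
      best <- list(threshold = t, rss = rss,
                   mean_below = mean(left), mean_above = mean(right))
  }
  inside_above <- best$mean_above >= best$mean_below
  structure(list(split = TRUE, threshold_depth = best$threshold,
                 mean_below = best$mean_below, mean_above = best$mean_above,
                 mean_inside = if (inside_above) best$mean_above else best$mean_below,
                 mean_outside = if (inside_above) best$mean_below else best$mean_above,
                 rss = best$rss, rss_null = rss_null),
            class = "depth_split")
}

#' @export
print.depth_split <- function(x, ...) {
  if (!x$split) {
    cat("Depth profile is constant; no split fitted\n")
  } else {
    cat(sprintf("Depth split at %.1f: mean %.2f below, %.2f above (RSS %.3f vs null %.3f)\n",
                x$threshold_depth, x$mean_below, x$mean_above,
                x$rss, x$rss_null))
  }
  invisible(x)
}
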