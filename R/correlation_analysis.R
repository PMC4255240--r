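# Pairwise SLN correlations between injections over common source areas,
# with the printed correlation matrices shipped as fixtures.

#' SLN pairs over common source areas of two injected targets
#'
#' For every source area projecting to both \code{target_a} and
#' \code{target_b} (excluding the two targets themselves and records with
#' missing SLN), returns the pair of SLN values.  When a table contains
#' replicate injections, pool them first (\code{\link{pool_injections}}).
#'
#' @param tab a \code{\link{connectivity_table}}.
#' @param target_a,target_b injected target areas.
#' @param area_filter optional character vector restricting the admissible
#'   source areas (exact names).
#' @return data frame with columns \code{source}, \code{sln_a}, \code{sln_b};
#'   zero rows when the source sets are disjoint.
#' @export
common_source_pairs <- function(tab, target_a, target_b, area_filter = NULL) {
  a <- tab[tab$target == target_a & !is.na(tab$sln), c("source", "sln")]
  b <- tab[tab$target == target_b & !is.na(tab$sln), c("source", "sln")]
  common <- setdiff(intersect(a$source, b$source), c(target_a, target_b))
  if (!is.null(area_filter)) common <- intersect(common, area_filter)
  common <- sort(common)
  data.frame(source = common,
             sln_a = a$sln[match(common, a$source)],
             sln_b = b$sln[match(common, b$source)],
             stringsAsFactors = FALSE)
}

#' Pairwise SLN correlation matrix across injected targets
#'
#' Pearson correlation, for every pair of injected target areas, of the SLN
#' values over their common source areas, on the raw or probit scale.  Pairs
#' with fewer than \code{min_support} common sources are reported as missing
#' (a correlation over 2 points is a +/-1 artifact), never as zero.
#'
#' @param tab a \code{\link{connectivity_table}}.
#' @param targets character vector of injected target areas.
#' @param scale \code{"raw"} (default) or \code{"probit"}
#'   (\code{\link{probit_sln}} applied to both members of each pair).
#' @param min_support minimum number of common sources (default 3).
#' @param eps probit clipping bound, see \code{\link{probit_sln}}.
#' @param area_filter optional restriction of admissible sources.
#' @return object of class \code{sln_cor}: list with the symmetric
#'   correlation matrix \code{r} (unit diagonal), the matrix of common-source
#'   counts \code{support}, and \code{scale}.
#' @export
sln_correlation_matrix <- function(tab, targets, scale = c("raw", "probit"),
                                   min_support = 3L, eps = 0.005,
                                   area_filter = NULL) {
  scale <- match.arg(scale)
  if (!all(targets %in% attr(tab, "areas")))
    stop("unknown target area(s): ",
         paste(setdiff(targets, attr(tab, "areas")), collapse = ", "))
  p <- length(targets)
  r <- diag(1, p); support <- diag(0L, p)
  dimnames(r) <- dimnames(support) <- list(targets, targets)
  for (i in seq_len(p - 1L)) for (j in seq((i + 1L), p)) {
    pr <- common_source_pairs(tab, targets[i], targets[j], area_filter)
    support[i, j] <- support[j, i] <- nrow(pr)
    if (nrow(pr) >= min_support) {
      x <- pr$sln_a; y <- pr$sln_b
      if (scale == "probit") { x <- probit_sln(x, eps); y <- probit_sln(y, eps) }
      r[i, j] <- r[j, i] <-
        if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
        else stats::cor(x, y)
    } else {
      r[i, j] <- r[j, i] <- NA_real_
    }
  }
  structure(list(r = r, support = support, scale = scale,
                 min_support = min_support),
            class = "sln_cor")
}

#' @export
print.sln_cor <- function(x, ...) {
  cat("SLN correlation matrix (", x$scale, " scale, ",
      nrow(x$r), " targets)\n", sep = "")
  print(round(x$r, 2))
  invisible(x)
}

.read_cor_fixture <- function(file, scale) {
  path <- system.file("extdata", file, package = "lamhier", mustWork = TRUE)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, fileEncoding = "UTF-8")
  m <- as.matrix(raw[, -1])
  rownames(m) <- raw[[1]]
  stopifnot(isSymmetric(m), all(diag(m) == 1))
  structure(list(r = m, support = NULL, scale = scale, min_support = NA),
            class = "sln_cor")
}

#' Published raw-scale SLN correlation matrix (11 injected areas)
#'
#' The printed pairwise correlation matrix of raw SLN values over common
#' sources, shipped as a fixture in its own right: recomputing it from the
#' SLN/distance table depends on inclusion rules that are not published, so
#' summary statistics are validated against this matrix directly.
#'
#' @return an \code{sln_cor} object (no support counts are published).
#' @export
load_table3 <- function()
  .read_cor_fixture("table3_sln_correlations.tsv", "raw")

#' Published probit-scale SLN correlation matrix (11 injected areas)
#'
#' Probit-transformed counterpart of \code{\link{load_table3}}.
#'
#' @return an \code{sln_cor} object.
#' @export
load_table4 <- function()
  .read_cor_fixture("table4_probit_correlations.tsv", "probit")

#' Summary statistics of a correlation matrix
#'
#' Statistics over the unique off-diagonal entries (upper triangle) of a
#' correlation matrix, optionally restricted to a subset of areas.  Missing
#' entries are dropped.  Quartiles use the linear-interpolation convention at
#' position \code{1 + (m - 1) p} (R quantile type 7), which reproduces the
#' published interquartile ranges.
#'
#' @param x an \code{sln_cor} object or a square correlation matrix.
#' @param subset optional character vector of area names.
#' @return named vector: \code{n}, \code{min}, \code{q1}, \code{median},
#'   \code{mean}, \code{q3}, \code{max}.
#' @export
correlation_summary <- function(x, subset = NULL) {
  m <- if (inherits(x, "sln_cor")) x$r else as.matrix(x)
  stopifnot(nrow(m) == ncol(m))
  if (!is.null(subset)) {
    miss <- setdiff(subset, rownames(m))
    if (length(miss)) stop("subset area(s) not in matrix: ",
                           paste(miss, collapse = ", "))
    m <- m[subset, subset, drop = FALSE]
  }
  v <- m[upper.tri(m)]
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("no off-diagonal entries selected")
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(n = length(v), min = min(v), q1 = q[1], median = q[2],
    mean = mean(v), q3 = q[3], max = max(v))
}

#' Fit a line to paired SLN values
#'
#' \code{"unit_slope"}: best-fitting line of slope exactly 1 (intercept is
#' \code{mean(y - x)}), the prediction of the strong hypothesis that SLN
#' differences are a rigid ruler of hierarchical distance.
#' \code{"major_axis"}: the line dually minimizing distance from the points
#' in both axes -- the first principal axis of the centered pairs.
#'
#' @param x,y paired coordinates, or \code{x} a data frame from
#'   \code{\link{common_source_pairs}} (columns \code{sln_a}, \code{sln_b}).
#' @param kind \code{"unit_slope"} or \code{"major_axis"}.
#' @return list of class \code{line_fit} with \code{slope}, \code{intercept}
#'   and \code{kind}.
#' @export
fit_line <- function(x, y = NULL, kind = c("unit_slope", "major_axis")) {
  kind <- match.arg(kind)
  if (is.null(y)) { y <- x$sln_b; x <- x$sln_a }
  stopifnot(length(x) == length(y))
  if (length(x) < 2) stop("at least 2 pairs are required")
  if (kind == "unit_slope") {
    out <- list(slope = 1, intercept = mean(y - x), kind = kind)
  } else {
    if (stats::var(x) == 0 && stats::var(y) == 0)
      stop("degenerate pairs: no variance in either coordinate")
    ev <- eigen(stats::cov(cbind(x, y)), symmetric = TRUE)
    v <- ev$vectors[, 1]
    if (v[1] == 0) stop("major axis is vertical; slope undefined")
    slope <- v[2] / v[1]
    out <- list(slope = slope, intercept = mean(y) - slope * mean(x),
                kind = kind)
  }
  structure(out, class = "line_fit")
}
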