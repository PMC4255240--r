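# SLN arithmetic, replicate pooling, probit transform, FF/FB classification.

#' Fraction of supragranular labeled neurons
#'
#' \code{SLN = S / (S + I)} for supragranular count \code{S} and infragranular
#' count \code{I}.  Vectorized.
#'
#' @param supra,infra non-negative integer counts.
#' @return SLN fraction(s) in [0, 1].
#' @export
compute_sln <- function(supra, infra) {
  if (any(supra < 0 | infra < 0)) stop("counts must be non-negative")
  if (any(supra + infra == 0)) stop("SLN undefined when both counts are zero")
  supra / (supra + infra)
}

#' Pool replicate injections by summing laminar counts
#'
#' Replicate projections of the same source-to-target pathway are combined by
#' adding the supra- and infragranular counts across injections and computing
#' SLN on the totals, which weights each injection by its size (NOT the mean
#' of per-replicate SLN values).  Distances are carried over (they are a
#' property of the area pair); FLN values, which are injection-normalized,
#' are averaged across replicates when present.
#'
#' @param tab a \code{\link{connectivity_table}} in which every record carries
#'   laminar counts.
#' @return a \code{connectivity_table} with one record per (target, source)
#'   pair and no \code{replicate} column content.
#' @export
pool_injections <- function(tab) {
  if (any(is.na(tab$supra) | is.na(tab$infra)))
    stop("pooling requires laminar counts on every record; ",
         "SLN-only records cannot be pooled")
  key <- paste(tab$target, tab$source, sep = "\r")
  agg <- function(x, f) as.vector(tapply(x, key, f))
  keys <- sort(unique(key))
  ord <- match(keys, sort(unique(key)))  # tapply sorts by key
  out <- data.frame(
    target = sub("\r.*$", "", keys),
    source = sub("^.*\r", "", keys),
    supra = agg(tab$supra, sum)[ord],
    infra = agg(tab$infra, sum)[ord],
    fln = agg(tab$fln, function(x) mean(x, na.rm = TRUE))[ord],
    distance_mm = agg(tab$distance_mm, function(x)
      if (all(is.na(x))) NA_real_ else x[!is.na(x)][1])[ord],
    stringsAsFactors = FALSE)
  out$fln[is.nan(out$fln)] <- NA_real_
  connectivity_table(out)
}

#' Probit transform of SLN
#'
#' Maps SLN to the real line through the inverse cumulative standard normal,
#' the scale on which hierarchical distance is modeled.  SLN values of
#' exactly 0 or 1 have an infinite probit; they are clipped to
#' \code{[eps, 1 - eps]} first.
#'
#' @param sln SLN fraction(s) in [0, 1].
#' @param eps clipping bound in (0, 0.5); default 0.005.
#' @return probit-scale value(s).
#' @export
probit_sln <- function(sln, eps = 0.005) {
  stopifnot(eps > 0, eps < 0.5)
  if (any(!is.na(sln) & (sln < 0 | sln > 1))) stop("sln must lie in [0, 1]")
  stats::qnorm(pmin(pmax(sln, eps), 1 - eps))
}

#' Classify pathways as feedforward or feedback from SLN
#'
#' Under the banded rule, pathways with \code{SLN >= upper} (default 0.55)
#' are feedforward (FF), those with \code{SLN <= lower} (default 0.45)
#' feedback (FB), and the open band in between is UNCLASSIFIED.  The
#' \code{"half"} rule instead cuts at 0.5 (FB strictly below, FF at or
#' above), leaving nothing unclassified; the hierarchy literature uses both
#' conventions.
#'
#' @param sln SLN fraction(s); missing values are an error.
#' @param rule \code{"band"} (default) or \code{"half"}.
#' @param lower,upper band edges for the banded rule.
#' @return factor with levels \code{FB}, \code{UNCLASSIFIED}, \code{FF}.
#' @export
classify_pathways <- function(sln, rule = c("band", "half"),
                              lower = 0.45, upper = 0.55) {
  rule <- match.arg(rule)
  if (any(is.na(sln))) stop("cannot classify a missing SLN")
  stopifnot(lower <= upper)
  lab <- if (rule == "band") {
    ifelse(sln >= upper, "FF", ifelse(sln <= lower, "FB", "UNCLASSIFIED"))
  } else {
    ifelse(sln >= 0.5, "FF", "FB")
  }
  factor(lab, levels = c("FB", "UNCLASSIFIED", "FF"))
}

#' Count pathways under source and target filters
#'
#' Number of records whose target is in \code{targets}, whose source is in
#' \code{sources} (exact name match), and whose SLN is not missing -- the
#' filter under which the published analysis of 339 visual-cortex pathways
#' is obtained from the packaged table
#' (\code{count_pathways(load_table2(), area_set("fve"), area_set("targets11"))}).
#'
#' @param tab a \code{\link{connectivity_table}}.
#' @param sources,targets character vectors of area names.
#' @return integer count.
#' @export
count_pathways <- function(tab, sources, targets) {
  sum(tab$target %in% targets & tab$source %in% sources & !is.na(tab$sln))
}
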