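# Weight-distance analyses: laminar-fractionated FLN regressions with a
# shared intercept, the FLN-SLN parabola, and FF/FB incidence and FLN
# balance by distance bin.

#' Split a projection's FLN into laminar parts
#'
#' The supragranular part is \code{sln * fln}, the infragranular part
#' \code{(1 - sln) * fln}; they sum to \code{fln} exactly.  Vectorized.
#'
#' @param sln SLN fraction(s).
#' @param fln FLN value(s); missing values are an error.
#' @return data frame with columns \code{supra_part}, \code{infra_part}.
#' @export
fractionate_fln <- function(sln, fln) {
  if (any(is.na(fln))) stop("fractionation requires an FLN value")
  if (any(is.na(sln))) stop("fractionation requires an SLN value")
  data.frame(supra_part = sln * fln, infra_part = (1 - sln) * fln)
}

#' Distance regression of laminar-fractionated FLN
#'
#' For pathways of one direction (FF or FB under the banded SLN rule), the
#' supragranular and infragranular FLN fractions are regressed on
#' white-matter distance jointly, with one intercept shared by the two layer
#' series and a separate slope per layer.  The reported F statistic compares
#' this constrained (3-parameter) model against the model with a separate
#' intercept per layer by the nested residual-sum-of-squares test; a second
#' F statistic tests the equality of the two layer slopes (common slope vs
#' separate slopes, intercept shared in both).  Fractions are analyzed on
#' log10 scale by default, consistent with the exponential decline of
#' connection weight with distance; zero fractions are floored at half the
#' smallest positive fraction with a warning.
#'
#' @param tab a \code{\link{connectivity_table}} with \code{sln}, \code{fln}
#'   and \code{distance_mm}.
#' @param direction \code{"FB"} or \code{"FF"} (banded classification).
#' @param transform \code{"log10"} (default) or \code{"identity"}.
#' @param zero_intercept if \code{TRUE}, the constrained model forces the
#'   shared intercept to zero (2 parameters) and the comparison model adds
#'   one free common intercept.
#' @param lower,upper FF/FB band edges, see \code{\link{classify_pathways}}.
#' @return object of class \code{distance_rule_fit}: \code{direction},
#'   \code{slope_supra}, \code{slope_infra}, their standard errors,
#'   \code{shared_intercept}, \code{f_stat}/\code{df}/\code{p_value}
#'   (intercept test), \code{f_slope}/\code{df_slope}/\code{p_slope}
#'   (slope-equality test), \code{n_pathways} and the model frame.
#' @export
fit_distance_rule <- function(tab, direction = c("FB", "FF"),
                              transform = c("log10", "identity"),
                              zero_intercept = FALSE,
                              lower = 0.45, upper = 0.55) {
  direction <- match.arg(direction)
  transform <- match.arg(transform)
  ok <- !is.na(tab$sln) & !is.na(tab$fln) & !is.na(tab$distance_mm)
  rec <- as.data.frame(tab)[ok, , drop = FALSE]
  cls <- classify_pathways(rec$sln, rule = "band", lower = lower, upper = upper)
  rec <- rec[cls == direction, , drop = FALSE]
  if (nrow(rec) < 4)
    stop("need at least 4 ", direction, " records with sln, fln and distance")
  parts <- fractionate_fln(rec$sln, rec$fln)
  dat <- data.frame(
    y = c(parts$supra_part, parts$infra_part),
    d = rep(rec$distance_mm, 2),
    layer = factor(rep(c("supra", "infra"), each = nrow(rec)),
                   levels = c("supra", "infra")))
  if (transform == "log10") {
    pos <- dat$y > 0
    if (!any(pos))
      stop("all fractions are zero; log10 transform impossible -- ",
           "supply identity transform or nonzero FLN fractions")
    if (any(!pos)) {
      floor_val <- min(dat$y[pos]) / 2
      warning(sum(!pos), " zero fraction(s) floored at ",
              signif(floor_val, 3), " before log10")
      dat$y[!pos] <- floor_val
    }
    dat$y <- log10(dat$y)
  }
  fit_c <- if (zero_intercept) stats::lm(y ~ 0 + d:layer, data = dat)
           else stats::lm(y ~ d:layer, data = dat)
  fit_u <- if (zero_intercept) stats::lm(y ~ 1 + d:layer, data = dat)
           else stats::lm(y ~ layer + d:layer, data = dat)
  rss_c <- sum(stats::residuals(fit_c)^2)
  rss_u <- sum(stats::residuals(fit_u)^2)
  df_u <- stats::df.residual(fit_u)
  # a perfect constrained fit carries no evidence for the larger model
  f <- if (rss_c <= 1e-12) 0 else max(0, (rss_c - rss_u)) / (rss_u / df_u)
  # slope-equality test within the shared-intercept family
  fit_s <- if (zero_intercept) stats::lm(y ~ 0 + d, data = dat)
           else stats::lm(y ~ d, data = dat)
  rss_s <- sum(stats::residuals(fit_s)^2)
  df_c <- stats::df.residual(fit_c)
  f_slope <- if (rss_c <= 1e-12) max(0, (rss_s - rss_c)) / 1e-12
             else max(0, (rss_s - rss_c)) / (rss_c / df_c)
  cf <- summary(fit_c)$coefficients
  sup_name <- "d:layersupra"; inf_name <- "d:layerinfra"
  structure(list(
    direction = direction, transform = transform,
    slope_supra = cf[sup_name, "Estimate"],
    slope_infra = cf[inf_name, "Estimate"],
    se_supra = cf[sup_name, "Std. Error"],
    se_infra = cf[inf_name, "Std. Error"],
    shared_intercept = if (zero_intercept) 0 else cf["(Intercept)", "Estimate"],
    f_stat = f, df = c(1L, df_u),
    p_value = stats::pf(f, 1, df_u, lower.tail = FALSE),
    f_slope = f_slope, df_slope = c(1L, df_c),
    p_slope = stats::pf(f_slope, 1, df_c, lower.tail = FALSE),
    n_pathways = nrow(rec), rss = c(constrained = rss_c, unconstrained = rss_u,
                                    common_slope = rss_s),
    data = dat), class = "distance_rule_fit")
}

#' @export
print.distance_rule_fit <- function(x, ...) {
  cat(x$direction, " distance rule (", x$transform, " scale, ",
      x$n_pathways, " pathways)\n", sep = "")
  cat(sprintf("  supra slope %.4f (se %.4f)/mm, infra slope %.4f (se %.4f)/mm\n",
              x$slope_supra, x$se_supra, x$slope_infra, x$se_infra))
  cat(sprintf("  shared intercept %.4f\n", x$shared_intercept))
  cat(sprintf("  intercept test: F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1], x$df[2], x$f_stat, x$p_value))
  cat(sprintf("  slope-equality test: F(%d, %d) = %.3f, p = %.4g\n",
              x$df_slope[1], x$df_slope[2], x$f_slope, x$p_slope))
  invisible(x)
}

#' Best-fitting parabola of log10 FLN against SLN
#'
#' Least-squares quadratic of \code{log10(fln)} on SLN.  Projections with
#' SLN near 0.5 (lateral or near-lateral) carry the largest weights, so the
#' fitted parabola opens downward with a vertex near mid-SLN when the
#' exponential distance rule holds.
#'
#' @param tab a \code{\link{connectivity_table}} with \code{sln}, \code{fln}.
#' @param grid SLN values at which the fitted curve and its pointwise
#'   standard-error band are evaluated.
#' @return list of class \code{fln_sln_parabola}: \code{coef} (intercept,
#'   linear, quadratic), \code{vertex} (SLN at the extremum), \code{band}
#'   (data frame \code{sln}, \code{fit}, \code{se}) and the \code{lm} model.
#' @export
fit_fln_sln_parabola <- function(tab, grid = seq(0, 1, by = 0.02)) {
  ok <- !is.na(tab$sln) & !is.na(tab$fln)
  rec <- as.data.frame(tab)[ok, , drop = FALSE]
  if (nrow(rec) < 5) stop("need at least 5 records with sln and fln")
  if (length(unique(rec$sln)) < 3 || stats::sd(rec$sln) < 1e-8)
    stop("degenerate SLN spread; parabola is unidentifiable")
  dat <- data.frame(lfln = log10(rec$fln), sln = rec$sln)
  fit <- stats::lm(lfln ~ sln + I(sln^2), data = dat)
  cf <- stats::coef(fit)
  vertex <- if (cf[3] == 0) NA_real_ else -cf[2] / (2 * cf[3])
  pr <- stats::predict(fit, newdata = data.frame(sln = grid), se.fit = TRUE)
  structure(list(coef = stats::setNames(cf, c("intercept", "linear",
                                              "quadratic")),
                 vertex = as.numeric(vertex),
                 band = data.frame(sln = grid, fit = pr$fit, se = pr$se.fit),
                 model = fit),
            class = "fln_sln_parabola")
}

# normalize bin specification to a two-column (lo, hi) matrix, check overlap
.normalize_bins <- function(bins) {
  if (is.numeric(bins) && is.null(dim(bins))) {
    if (length(bins) < 2 || is.unsorted(bins, strictly = TRUE))
      stop("numeric bin breaks must be strictly increasing")
    m <- cbind(bins[-length(bins)], bins[-1])
  } else {
    if (is.list(bins)) bins <- do.call(rbind, bins)
    m <- as.matrix(bins)
    if (ncol(m) != 2 || any(m[, 1] >= m[, 2]))
      stop("bins must be (lo, hi) intervals with lo < hi")
    o <- order(m[, 1])
    if (any(m[o, 2][-nrow(m)] > m[o, 1][-1]))
      stop("bins overlap")
  }
  dimnames(m) <- list(NULL, c("lo", "hi"))
  m
}

#' FF and FB pathway incidence by distance bin
#'
#' Counts feedforward and feedback pathways (banded SLN classification;
#' unclassified pathways are excluded) per half-open distance bin
#' \code{[lo, hi)}.
#'
#' @param tab a \code{\link{connectivity_table}} with \code{sln} and
#'   \code{distance_mm}.
#' @param bins strictly increasing numeric breaks, or a list/matrix of
#'   non-overlapping \code{(lo, hi)} intervals.
#' @param sources,targets optional exact-name area filters.
#' @param lower,upper FF/FB band edges.
#' @return data frame with columns \code{lo}, \code{hi}, \code{ff}, \code{fb}.
#' @export
incidence_by_distance <- function(tab, bins, sources = NULL, targets = NULL,
                                  lower = 0.45, upper = 0.55) {
  m <- .normalize_bins(bins)
  ok <- !is.na(tab$sln) & !is.na(tab$distance_mm)
  if (!is.null(sources)) ok <- ok & tab$source %in% sources
  if (!is.null(targets)) ok <- ok & tab$target %in% targets
  rec <- as.data.frame(tab)[ok, , drop = FALSE]
  cls <- classify_pathways(rec$sln, rule = "band", lower = lower, upper = upper)
  out <- data.frame(lo = m[, 1], hi = m[, 2], ff = 0L, fb = 0L)
  for (i in seq_len(nrow(m))) {
    inbin <- rec$distance_mm >= m[i, 1] & rec$distance_mm < m[i, 2]
    out$ff[i] <- sum(inbin & cls == "FF")
    out$fb[i] <- sum(inbin & cls == "FB")
  }
  out
}

#' FF-minus-FB FLN balance at short and long distances
#'
#' For each injected target area and each distance bin, the summed FLN
#' percentage of its FB pathways is subtracted from the summed FLN
#' percentage of its FF pathways.  The per-bin summary is the median of this
#' balance across targets with the median absolute deviation (raw MAD,
#' no consistency constant) as the error measure.  Bins are half-open
#' \code{[lo, hi)}.
#'
#' @param tab a \code{\link{connectivity_table}} with \code{sln}, \code{fln}
#'   and \code{distance_mm}.
#' @param short_bin,long_bin length-2 \code{(lo, hi)} distance intervals in
#'   mm; defaults 0-10 and 20-50.
#' @param lower,upper FF/FB band edges.
#' @return list with \code{per_target} (data frame target, bin, balance in
#'   FLN percentage points) and \code{summary} (per bin: median, mad, n).
#' @export
fln_balance_by_distance <- function(tab, short_bin = c(0, 10),
                                    long_bin = c(20, 50),
                                    lower = 0.45, upper = 0.55) {
  if (all(is.na(tab$fln))) stop("table carries no FLN values")
  ok <- !is.na(tab$sln) & !is.na(tab$fln) & !is.na(tab$distance_mm)
  rec <- as.data.frame(tab)[ok, , drop = FALSE]
  cls <- classify_pathways(rec$sln, rule = "band", lower = lower, upper = upper)
  bins <- list(short = short_bin, long = long_bin)
  rows <- list()
  for (bn in names(bins)) {
    b <- bins[[bn]]
    inbin <- rec$distance_mm >= b[1] & rec$distance_mm < b[2]
    for (tg in sort(unique(rec$target))) {
      sel <- inbin & rec$target == tg
      if (!any(sel)) next
      bal <- 100 * (sum(rec$fln[sel & cls == "FF"]) -
                      sum(rec$fln[sel & cls == "FB"]))
      rows[[length(rows) + 1L]] <-
        data.frame(target = tg, bin = bn, balance = bal,
                   stringsAsFactors = FALSE)
    }
  }
  per_target <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(names(bins), function(bn) {
    v <- per_target$balance[per_target$bin == bn]
    data.frame(bin = bn,
               median = if (length(v)) stats::median(v) else NA_real_,
               mad = if (length(v)) stats::mad(v, constant = 1) else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  }))
  list(per_target = per_target, summary = summ)
}
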