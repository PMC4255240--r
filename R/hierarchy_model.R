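# Beta-binomial probit hierarchy model on the incidence matrix of the
# cortical graph, plus the identity-link least-squares alternative.

#' Incidence matrix of the cortical graph
#'
#' One row per projection (edge), one column per area (node), with -1 at the
#' source column and +1 at the target column, so that \code{X \%*\% beta} is
#' the target-minus-source difference of hierarchical levels.  Every row of
#' the full matrix sums to zero, so the matrix is singular; the column of
#' \code{drop_area} is deleted, fixing that area's level at 0 and making the
#' model identifiable.  Replicate records enter as separate rows.
#'
#' @param tab a \code{\link{connectivity_table}}; every record becomes an edge.
#' @param drop_area area whose column is deleted (the reference area).
#' @return list of class \code{incidence_matrix} with elements \code{X}
#'   (n_edges x (p-1), columns named by estimated areas), \code{X_full}
#'   (before deletion), \code{areas}, \code{dropped_area} and \code{edges}
#'   (data frame of source/target per row).
#' @export
build_incidence <- function(tab, drop_area) {
  areas <- attr(tab, "areas")
  if (is.null(areas)) areas <- sort(unique(c(tab$target, tab$source)))
  if (!drop_area %in% areas)
    stop("drop_area '", drop_area, "' does not appear in the table")
  n <- nrow(tab)
  X <- matrix(0, n, length(areas), dimnames = list(NULL, areas))
  X[cbind(seq_len(n), match(tab$source, areas))] <- -1
  X[cbind(seq_len(n), match(tab$target, areas))] <- +1
  structure(list(X = X[, setdiff(areas, drop_area), drop = FALSE],
                 X_full = X, areas = areas, dropped_area = drop_area,
                 edges = data.frame(source = tab$source, target = tab$target,
                                    stringsAsFactors = FALSE)),
            class = "incidence_matrix")
}

#' Beta-binomial log probability mass
#'
#' Log of \code{choose(n, k) * B(k + a, n - k + b) / B(a, b)} with
#' \code{a = mu * (1 - phi) / phi} and \code{b = (1 - mu) * (1 - phi) / phi},
#' the mean/dispersion parameterization under which the variance of the
#' proportion \code{k / n} is \code{(1/n) mu (1 - mu) (1 + (n - 1) phi)}.
#' At \code{phi = 0} the analytic binomial limit is returned.  Vectorized
#' over all arguments.
#'
#' @param k number of supragranular neurons (successes), \code{0 <= k <= n}.
#' @param n total neuron count, \code{n >= 1}.
#' @param mu mean proportion in (0, 1).
#' @param phi dispersion in [0, 1).
#' @return log probability mass.
#' @export
betabin_logpmf <- function(k, n, mu, phi) {
  m <- max(length(k), length(n), length(mu), length(phi))
  k <- rep_len(k, m); n <- rep_len(n, m)
  mu <- rep_len(mu, m); phi <- rep_len(phi, m)
  if (any(k < 0 | k > n)) stop("k must lie in [0, n]")
  if (any(mu <= 0 | mu >= 1)) stop("mu must lie in (0, 1)")
  if (any(phi < 0 | phi >= 1)) stop("phi must lie in [0, 1)")
  out <- numeric(m)
  b0 <- phi == 0
  if (any(b0)) out[b0] <- stats::dbinom(k[b0], n[b0], mu[b0], log = TRUE)
  if (any(!b0)) {
    a <- mu[!b0] * (1 - phi[!b0]) / phi[!b0]
    b <- (1 - mu[!b0]) * (1 - phi[!b0]) / phi[!b0]
    out[!b0] <- lchoose(n[!b0], k[!b0]) +
      lbeta(k[!b0] + a, n[!b0] - k[!b0] + b) - lbeta(a, b)
  }
  out
}

# negative log likelihood over the dataset; par = (beta, qlogis(phi))
.betabin_nll <- function(par, k, n, X) {
  p <- ncol(X)
  beta <- par[seq_len(p)]
  phi <- stats::plogis(par[p + 1L])
  mu <- stats::pnorm(as.vector(X %*% beta))
  mu <- pmin(pmax(mu, 1e-9), 1 - 1e-9)
  -sum(betabin_logpmf(k, n, mu, phi))
}

# negative log likelihood on the natural (beta, phi) scale, for the Hessian
.betabin_nll_nat <- function(par, k, n, X) {
  p <- ncol(X)
  mu <- stats::pnorm(as.vector(X %*% par[seq_len(p)]))
  mu <- pmin(pmax(mu, 1e-9), 1 - 1e-9)
  phi <- min(max(par[p + 1L], 1e-9), 1 - 1e-9)
  -sum(betabin_logpmf(k, n, mu, phi))
}

# central finite-difference Hessian, relative step
.fd_hessian <- function(f, x, rel_step = 1e-4, ...) {
  m <- length(x)
  h <- rel_step * pmax(abs(x), 1)
  H <- matrix(0, m, m)
  f0 <- f(x, ...)
  for (i in seq_len(m)) {
    ei <- numeric(m); ei[i] <- h[i]
    H[i, i] <- (f(x + ei, ...) - 2 * f0 + f(x - ei, ...)) / h[i]^2
    if (i < m) for (j in seq((i + 1L), m)) {
      ej <- numeric(m); ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej, ...) - f(x + ei - ej, ...) -
           f(x - ei + ej, ...) + f(x - ei - ej, ...)) / (4 * h[i] * h[j])
    }
  }
  H
}

# error if the undirected support graph is disconnected
.check_connected <- function(edges, areas) {
  g <- igraph::graph_from_data_frame(edges[, c("source", "target")],
                                     directed = FALSE,
                                     vertices = data.frame(name = areas))
  comp <- igraph::components(g)
  if (comp$no > 1) {
    small <- names(comp$membership)[comp$membership != which.max(comp$csize)]
    stop("graph is disconnected; component not reachable from the rest: ",
         paste(small, collapse = ", "))
  }
  invisible(TRUE)
}

.new_hierarchy_fit <- function(levels, se, phi, phi_se, loglik, converged,
                               link, dropped_area, extra = list()) {
  structure(c(list(levels = levels, se = se, phi = phi, phi_se = phi_se,
                   loglik = loglik, converged = converged, link = link,
                   dropped_area = dropped_area,
                   levels_raw = levels, se_raw = se,
                   scale = c(offset = 0, slope = 1)),
              extra),
            class = "hierarchy_fit")
}

#' Maximum-likelihood hierarchy estimation under the beta-binomial model
#'
#' Estimates per-area hierarchical levels \code{beta} and the dispersion
#' \code{phi} by maximizing the beta-binomial log likelihood with mean
#' \code{mu = pnorm(X beta)} per edge (probit link).  Optimization uses
#' Nelder-Mead on \code{(beta, qlogis(phi))}, which keeps \code{phi} in
#' (0, 1), followed by restarts from the incumbent until the objective is
#' stable.  Standard errors come from the inverse of the central
#' finite-difference Hessian of the negative log likelihood with respect to
#' \code{(beta, phi)} at the optimum.
#'
#' @param k supragranular count per edge.
#' @param n total count per edge (\code{n >= 1}).
#' @param inc an \code{\link{build_incidence}} result.
#' @param init optional start values for \code{beta} (default all 0).
#' @param phi_init start value for \code{phi} (default 0.1).
#' @param reltol relative convergence tolerance on the objective.
#' @param maxit maximum Nelder-Mead iterations per start.
#' @param restarts number of Nelder-Mead restarts from the incumbent.
#' @param refine if \code{TRUE} (default), polish the Nelder-Mead solution
#'   with a quasi-Newton (BFGS) pass; the refined solution is kept only when
#'   it improves the objective.  Nelder-Mead alone can stall short of the
#'   optimum in this dimension.
#' @return an object of class \code{hierarchy_fit} with named per-area
#'   \code{levels} (reference area at 0) and \code{se} (reference at 0),
#'   \code{phi}, \code{phi_se}, \code{loglik}, and a \code{converged} flag.
#' @export
fit_hierarchy_betabin <- function(k, n, inc, init = NULL, phi_init = 0.1,
                                  reltol = 1e-8, maxit = 20000L,
                                  restarts = 2L, refine = TRUE) {
  stopifnot(inherits(inc, "incidence_matrix"))
  X <- inc$X
  if (length(k) != nrow(X) || length(n) != nrow(X))
    stop("k and n must have one value per edge")
  if (any(is.na(k) | is.na(n)) || any(n < 1) || any(k < 0 | k > n))
    stop("every edge needs counts with 0 <= k <= n and n >= 1")
  .check_connected(inc$edges, inc$areas)
  p <- ncol(X)
  beta0 <- if (is.null(init)) numeric(p) else rep_len(init, p)
  par <- c(beta0, stats::qlogis(phi_init))
  opt <- NULL
  for (r in seq_len(restarts + 1L)) {
    opt <- stats::optim(par, .betabin_nll, k = k, n = n, X = X,
                        method = "Nelder-Mead",
                        control = list(reltol = reltol, maxit = maxit))
    if (!is.null(opt) && r > 1L && opt$value > prev_value - 1e-10) break
    prev_value <- opt$value
    par <- opt$par
  }
  if (refine) {
    pol <- stats::optim(opt$par, .betabin_nll, k = k, n = n, X = X,
                        method = "BFGS",
                        control = list(reltol = 1e-12, maxit = 1000L))
    if (pol$value < opt$value) {
      pol$convergence <- 0L  # improved on the accepted Nelder-Mead solution
      opt <- pol
    }
  }
  beta_hat <- opt$par[seq_len(p)]
  phi_hat <- stats::plogis(opt$par[p + 1L])
  H <- .fd_hessian(.betabin_nll_nat, c(beta_hat, phi_hat),
                   rel_step = 1e-4, k = k, n = n, X = X)
  cov <- tryCatch(solve(H), error = function(e) NULL)
  se_all <- if (is.null(cov)) rep(NA_real_, p + 1L) else {
    d <- diag(cov)
    ifelse(d > 0, sqrt(d), NA_real_)
  }
  areas <- inc$areas
  levels <- stats::setNames(numeric(length(areas)), areas)
  se <- stats::setNames(numeric(length(areas)), areas)
  levels[colnames(X)] <- beta_hat
  se[colnames(X)] <- se_all[seq_len(p)]
  .new_hierarchy_fit(levels, se, phi_hat, se_all[p + 1L],
                     loglik = -opt$value,
                     converged = opt$convergence == 0,
                     link = "probit", dropped_area = inc$dropped_area,
                     extra = list(counts = list(k = k, n = n),
                                  optim = opt[c("convergence", "counts")]))
}

#' Least-squares hierarchy estimation with the identity link
#'
#' Solves \code{Y = X beta} by ordinary least squares on the raw SLN values,
#' the identity-link alternative in which SLN differences are treated
#' directly as hierarchical distances.  Identifiability is handled exactly as
#' in the beta-binomial fit (reference-area column deleted).
#'
#' @param y SLN fraction per edge.
#' @param inc an \code{\link{build_incidence}} result.
#' @return an object of class \code{hierarchy_fit} (link \code{"identity"});
#'   \code{loglik} is the Gaussian profile log likelihood at the OLS solution.
#' @export
fit_hierarchy_linear <- function(y, inc) {
  stopifnot(inherits(inc, "incidence_matrix"))
  X <- inc$X
  if (length(y) != nrow(X)) stop("y must have one value per edge")
  if (any(is.na(y))) stop("every edge needs an SLN value")
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("design is rank deficient beyond the deleted reference column")
  beta_hat <- qr.coef(qrX, y)
  res <- y - as.vector(X %*% beta_hat)
  rss <- sum(res^2)
  ne <- nrow(X)
  dfres <- ne - ncol(X)
  sigma2 <- if (dfres > 0) rss / dfres else NA_real_
  XtXinv <- chol2inv(qr.R(qrX))
  se_hat <- if (is.na(sigma2)) rep(NA_real_, ncol(X)) else
    sqrt(sigma2 * diag(XtXinv))
  areas <- inc$areas
  levels <- stats::setNames(numeric(length(areas)), areas)
  se <- stats::setNames(numeric(length(areas)), areas)
  levels[colnames(X)] <- beta_hat
  se[colnames(X)] <- se_hat
  ll <- -ne / 2 * (log(2 * pi * rss / ne) + 1)
  .new_hierarchy_fit(levels, se, phi = NA_real_, phi_se = NA_real_,
                     loglik = ll, converged = TRUE, link = "identity",
                     dropped_area = inc$dropped_area,
                     extra = list(rss = rss, sln = y))
}

#' Predicted SLN per edge from a hierarchy fit
#'
#' Probit-link fits predict \code{pnorm(X beta)}; identity-link fits predict
#' \code{X beta} clipped to [0, 1].  Predictions use the unscaled levels, so
#' they are unchanged by \code{\link{rescale_levels}}.
#'
#' @param fit a \code{hierarchy_fit}.
#' @param inc an \code{\link{build_incidence}} result sharing the fit's areas.
#' @return vector of predicted SLN fractions, one per edge.
#' @export
predict_sln <- function(fit, inc) {
  stopifnot(inherits(fit, "hierarchy_fit"), inherits(inc, "incidence_matrix"))
  if (!all(inc$areas %in% names(fit$levels_raw)))
    stop("fit and incidence matrix do not share the same areas")
  eta <- as.vector(inc$X_full %*% fit$levels_raw[inc$areas])
  if (fit$link == "probit") stats::pnorm(eta) else pmin(pmax(eta, 0), 1)
}

#' Compare the predictive accuracy of two hierarchy fits
#'
#' Compares the Pearson correlation between observed and predicted SLN for
#' two fits of the same edges.  Because the two correlations share the
#' observed variable, the default method bootstraps edges: the difference
#' \code{r_a - r_b} is recomputed over \code{B} resamples and the z statistic
#' is the observed difference divided by its bootstrap standard deviation.
#' A positive statistic favors \code{fit_a}.
#'
#' @param y observed SLN per edge.
#' @param fit_a,fit_b two \code{hierarchy_fit} objects.
#' @param inc incidence matrix shared by both fits.
#' @param method only \code{"bootstrap"} is implemented.
#' @param B number of bootstrap resamples.
#' @param seed optional integer seed for reproducible resampling.
#' @return list with \code{statistic}, \code{p_value}, \code{r_a}, \code{r_b},
#'   \code{method} and \code{B}.
#' @export
compare_models <- function(y, fit_a, fit_b, inc, method = "bootstrap",
                           B = 2000L, seed = NULL) {
  method <- match.arg(method, "bootstrap")
  ne <- length(y)
  if (ne < 10) stop("model comparison needs at least 10 edges")
  pa <- predict_sln(fit_a, inc)
  pb <- predict_sln(fit_b, inc)
  r_a <- stats::cor(y, pa)
  r_b <- stats::cor(y, pb)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  diffs <- replicate(B, {
    i <- sample.int(ne, replace = TRUE)
    suppressWarnings(stats::cor(y[i], pa[i]) - stats::cor(y[i], pb[i]))
  })
  diffs <- diffs[is.finite(diffs)]
  sd_d <- stats::sd(diffs)
  if (!is.finite(sd_d) || sd_d == 0) {
    z <- 0; p <- 1
  } else {
    z <- (r_a - r_b) / sd_d
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(statistic = z, p_value = p, r_a = r_a, r_b = r_b,
       method = "bootstrap", B = B)
}

#' Rescale hierarchical levels to a reporting range
#'
#' Affine map sending the lowest level to \code{lo} and the highest to
#' \code{hi} (conventionally 1 to 10).  Standard errors are multiplied by
#' the same positive factor.  The unscaled levels are retained, so
#' \code{\link{predict_sln}} is unaffected, and rescaling is idempotent.
#'
#' @param fit a \code{hierarchy_fit}.
#' @param lo,hi target range, \code{hi > lo}.
#' @return the fit with rescaled \code{levels} and \code{se}.
#' @export
rescale_levels <- function(fit, lo = 1, hi = 10) {
  stopifnot(inherits(fit, "hierarchy_fit"), hi > lo)
  rng <- range(fit$levels_raw)
  if (diff(rng) == 0)
    stop("all levels are equal; rescaling is undefined")
  slope <- (hi - lo) / diff(rng)
  fit$levels <- lo + (fit$levels_raw - rng[1]) * slope
  fit$se <- fit$se_raw * slope
  fit$scale <- c(offset = lo - rng[1] * slope, slope = slope)
  fit
}

#' @export
print.hierarchy_fit <- function(x, ...) {
  cat("Hierarchy fit (", x$link, " link), reference area ",
      x$dropped_area, "\n", sep = "")
  if (!is.na(x$phi))
    cat("dispersion phi =", format(x$phi, digits = 4),
        if (!is.na(x$phi_se)) paste0("(se ", format(x$phi_se, digits = 3), ")"),
        "\n")
  cat("log-likelihood =", format(x$loglik, digits = 6),
      if (!x$converged) " [NOT CONVERGED]", "\n")
  ord <- order(x$levels)
  print(round(data.frame(level = x$levels[ord], se = x$se[ord]), 3))
  invisible(x)
}

#' Fit a cortical hierarchy from a connectivity table
#'
#' High-level wrapper: filters records, pools nothing (records enter as
#' separate edges), checks that the graph is connected (areas unreachable
#' from \code{drop_area} on the undirected support are dropped with a
#' warning), builds the incidence matrix and dispatches to
#' \code{\link{fit_hierarchy_betabin}} or \code{\link{fit_hierarchy_linear}}.
#' For beta-binomial fits on tables that carry only SLN (no laminar counts),
#' counts are synthesized as \code{k = round(sln * n_eff)}, \code{n = n_eff};
#' such fits are flagged \code{approximate} because the true counts are
#' unavailable.
#'
#' @param tab a \code{\link{connectivity_table}}.
#' @param model \code{"betabin"} (default) or \code{"linear"}.
#' @param drop_area reference area fixed at level 0 (default \code{"V1"}).
#' @param sources,targets optional exact-name area filters on records.
#' @param n_eff effective total count per edge used when counts are absent.
#' @param rescale length-2 numeric reporting range, or \code{NULL} to skip.
#' @param ... passed to the underlying fitting function.
#' @return a \code{hierarchy_fit}.
#' @export
fit_hierarchy <- function(tab, model = c("betabin", "linear"),
                          drop_area = "V1", sources = NULL, targets = NULL,
                          n_eff = 100L, rescale = c(1, 10), ...) {
  model <- match.arg(model)
  keep <- !is.na(tab$sln) | (!is.na(tab$supra) & !is.na(tab$infra))
  if (!is.null(sources)) keep <- keep & tab$source %in% sources
  if (!is.null(targets)) keep <- keep & tab$target %in% targets
  rec <- as.data.frame(tab)[keep, , drop = FALSE]
  if (nrow(rec) == 0) stop("no usable records after filtering")
  # drop areas unreachable from the reference on the undirected support
  areas <- sort(unique(c(rec$target, rec$source)))
  if (!drop_area %in% areas)
    stop("reference area '", drop_area, "' not present after filtering")
  g <- igraph::graph_from_data_frame(rec[, c("source", "target")],
                                     directed = FALSE,
                                     vertices = data.frame(name = areas))
  comp <- igraph::components(g)
  ref_comp <- comp$membership[[drop_area]]
  if (comp$no > 1) {
    dropped <- names(comp$membership)[comp$membership != ref_comp]
    warning("dropping ", length(dropped),
            " area(s) not connected to the reference: ",
            paste(dropped, collapse = ", "))
    rec <- rec[rec$source %in% names(comp$membership)[comp$membership == ref_comp] &
                 rec$target %in% names(comp$membership)[comp$membership == ref_comp], ]
  }
  sub <- connectivity_table(rec)
  inc <- build_incidence(sub, drop_area)
  approx_counts <- FALSE
  if (model == "betabin") {
    if (any(is.na(sub$supra) | is.na(sub$infra))) {
      approx_counts <- TRUE
      n <- rep(as.integer(n_eff), nrow(sub))
      k <- as.integer(round(sub$sln * n_eff))
      has <- !is.na(sub$supra) & !is.na(sub$infra)
      k[has] <- sub$supra[has]
      n[has] <- sub$supra[has] + sub$infra[has]
    } else {
      k <- sub$supra
      n <- sub$supra + sub$infra
    }
    fit <- fit_hierarchy_betabin(k, n, inc, ...)
  } else {
    fit <- fit_hierarchy_linear(sub$sln, inc)
  }
  fit$approximate <- approx_counts
  if (approx_counts) fit$n_eff <- n_eff
  if (!is.null(rescale)) fit <- rescale_levels(fit, rescale[1], rescale[2])
  fit
}
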