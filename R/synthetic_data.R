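# Seeded synthetic tracing data with the statistical structure the analyses
# assume: probit-of-hierarchy SLN means, beta-binomial laminar counts, and
# exponential-distance-rule projection weights.

#' Beta-binomial random deviates (mean/dispersion parameterization)
#'
#' Draws \code{k ~ BetaBinomial(size, mu, phi)} by sampling a per-draw
#' success probability from \code{Beta(mu (1-phi)/phi, (1-mu)(1-phi)/phi)}
#' and then a binomial count.  At \code{phi = 0} this is a plain binomial.
#'
#' @param n number of draws.
#' @param size total count per draw.
#' @param mu mean proportion in (0, 1).
#' @param phi dispersion in [0, 1).
#' @return integer vector of counts.
#' @export
rbetabinom <- function(n, size, mu, phi) {
  if (any(mu <= 0 | mu >= 1)) stop("mu must lie in (0, 1)")
  if (any(phi < 0 | phi >= 1)) stop("phi must lie in [0, 1)")
  size <- rep_len(size, n); mu <- rep_len(mu, n); phi <- rep_len(phi, n)
  p <- ifelse(phi == 0, mu,
              stats::rbeta(n, mu * (1 - phi) / phi,
                           (1 - mu) * (1 - phi) / phi))
  stats::rbinom(n, size, p)
}

#' Configuration for the synthetic tracing generator
#'
#' Defaults mirror the scale of the packaged macaque dataset: 11 areas,
#' hierarchical levels spread over about 2.5 probit units (so SLN spans its
#' full range), dispersion \code{phi = 0.1}, an edge density of 0.9 (the
#' packaged table realizes 99 of the 110 ordered pairs among its 11 injected
#' areas), 100 neurons counted per projection, area centers placed uniformly
#' in a 40 mm cube (pairwise distances of roughly 4-46 mm) and an
#' exponential distance rule for weights with decay 0.19 per mm.
#'
#' @param n_areas number of areas p.
#' @param true_levels optional numeric vector of length p; when \code{NULL},
#'   levels are drawn uniformly on \code{[0, level_span]}.
#' @param level_span span of random levels (probit units).
#' @param phi beta-binomial dispersion in [0, 1).
#' @param counts_per_edge total neurons counted per projection: a scalar, a
#'   vector recycled over edges, or a function of the number of edges.
#' @param edge_density probability that an ordered pair of areas is realized
#'   as a projection.
#' @param fb_bias directional asymmetry in (-1, 1): positive values make
#'   descending edges (expected SLN below 0.5) proportionally more likely,
#'   mimicking the observed preponderance of feedback pathways.
#' @param box_mm side of the cube in which area centers are placed.
#' @param distances optional user-supplied symmetric distance matrix
#'   (mm, \code{n_areas} square) overriding the random geometry.
#' @param edr_lambda weight decay rate per mm.
#' @param edr_lambda_ff,edr_lambda_fb optional direction-specific decay
#'   rates (default \code{edr_lambda} for both); setting
#'   \code{edr_lambda_ff > edr_lambda_fb} makes feedback weights dominate at
#'   long range, as observed.
#' @param edr_amp_ff,edr_amp_fb direction-specific weight amplitudes at zero
#'   distance (default 1).  With \code{edr_amp_ff > edr_amp_fb} and
#'   \code{edr_lambda_ff > edr_lambda_fb} the two weight curves cross:
#'   feedforward weight dominates short-range pathways and feedback weight
#'   long-range ones, the combinatorial distance rule of the counterstream.
#' @param noise_sd_logfln standard deviation of the log-normal weight noise
#'   (natural-log scale).
#' @param seed integer seed governing all randomness.
#' @return validated list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_areas = 11L, true_levels = NULL,
                             level_span = 2.5, phi = 0.1,
                             counts_per_edge = 100L, edge_density = 0.9,
                             fb_bias = 0, box_mm = 40, distances = NULL,
                             edr_lambda = 0.19, edr_lambda_ff = NULL,
                             edr_lambda_fb = NULL, edr_amp_ff = 1,
                             edr_amp_fb = 1, noise_sd_logfln = 1,
                             seed = 1L) {
  stopifnot(n_areas >= 2, phi >= 0, phi < 1, edge_density > 0,
            edge_density <= 1, level_span > 0, box_mm > 0,
            edr_lambda > 0, noise_sd_logfln >= 0,
            edr_amp_ff > 0, edr_amp_fb > 0,
            fb_bias > -1, fb_bias < 1)
  if (!is.null(true_levels) && length(true_levels) != n_areas)
    stop("true_levels must have length n_areas")
  if (!is.null(distances)) {
    distances <- as.matrix(distances)
    stopifnot(nrow(distances) == n_areas, isSymmetric(unname(distances)),
              all(distances[upper.tri(distances)] > 0))
  }
  structure(list(n_areas = as.integer(n_areas), true_levels = true_levels,
                 level_span = level_span, phi = phi,
                 counts_per_edge = counts_per_edge,
                 edge_density = edge_density, fb_bias = fb_bias,
                 box_mm = box_mm, distances = distances,
                 edr_lambda = edr_lambda,
                 edr_lambda_ff = if (is.null(edr_lambda_ff)) edr_lambda
                                 else edr_lambda_ff,
                 edr_lambda_fb = if (is.null(edr_lambda_fb)) edr_lambda
                                 else edr_lambda_fb,
                 edr_amp_ff = edr_amp_ff, edr_amp_fb = edr_amp_fb,
                 noise_sd_logfln = noise_sd_logfln,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# run expr under a stage-specific seed, restoring the caller's RNG state
.with_stage_seed <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed((seed %% 1000003L) * 1009L + stage)
  expr
}

#' Generate a synthetic tracing dataset
#'
#' For each realized directed edge i -> j the expected SLN is
#' \code{mu = pnorm(beta_j - beta_i)} (the model the hierarchy fit inverts),
#' the supragranular count is beta-binomial with dispersion \code{phi}, and
#' the projection weight declines exponentially with the distance between
#' the (randomly placed or user-supplied) area centers under log-normal
#' noise, normalized so FLN sums to 1 per target.  All randomness derives
#' deterministically from \code{config$seed}; the same configuration always
#' yields an identical dataset, and the caller's RNG state is untouched.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return list of class \code{synthetic_tracing}: \code{table} (a
#'   \code{\link{connectivity_table}} with counts, sln, fln, distances),
#'   \code{truth} (named \code{levels}, \code{phi}, \code{positions}) and
#'   \code{config}.
#' @export
simulate_tracing <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  p <- config$n_areas
  areas <- sprintf("A%02d", seq_len(p))
  levels <- .with_stage_seed(config$seed, 1L, {
    if (is.null(config$true_levels))
      stats::runif(p, 0, config$level_span) else config$true_levels
  })
  names(levels) <- areas
  if (is.null(config$distances)) {
    pos <- .with_stage_seed(config$seed, 2L,
      matrix(stats::runif(3 * p, 0, config$box_mm), ncol = 3))
    D <- as.matrix(stats::dist(pos))
  } else {
    pos <- NULL
    D <- config$distances
  }
  dimnames(D) <- list(areas, areas)
  pairs <- expand.grid(source = seq_len(p), target = seq_len(p))
  pairs <- pairs[pairs$source != pairs$target, ]
  mu_all <- stats::pnorm(levels[pairs$target] - levels[pairs$source])
  p_edge <- config$edge_density *
    ifelse(mu_all < 0.5, 1 + config$fb_bias, 1 - config$fb_bias)
  p_edge <- pmin(pmax(p_edge, 0), 1)
  keep <- .with_stage_seed(config$seed, 3L,
    stats::runif(nrow(pairs)) < p_edge)
  if (!any(keep)) stop("no edges realized; increase edge_density")
  pairs <- pairs[keep, ]
  mu <- pmin(pmax(mu_all[keep], 1e-9), 1 - 1e-9)
  ne <- nrow(pairs)
  n_tot <- if (is.function(config$counts_per_edge))
    config$counts_per_edge(ne) else rep_len(config$counts_per_edge, ne)
  n_tot <- as.integer(n_tot)
  stopifnot(all(n_tot >= 1))
  k <- .with_stage_seed(config$seed, 4L,
    rbetabinom(ne, n_tot, mu, config$phi))
  d <- D[cbind(pairs$source, pairs$target)]
  is_ff <- mu >= 0.5
  lambda <- ifelse(is_ff, config$edr_lambda_ff, config$edr_lambda_fb)
  amp <- ifelse(is_ff, config$edr_amp_ff, config$edr_amp_fb)
  w <- .with_stage_seed(config$seed, 5L,
    amp * exp(-lambda * d) * stats::rlnorm(ne, 0, config$noise_sd_logfln))
  fln <- w / as.vector(tapply(w, pairs$target, sum)[as.character(pairs$target)])
  tab <- connectivity_table(data.frame(
    target = areas[pairs$target], source = areas[pairs$source],
    supra = k, infra = n_tot - k, fln = fln, distance_mm = d,
    stringsAsFactors = FALSE))
  structure(list(table = tab,
                 truth = list(levels = levels, phi = config$phi,
                              positions = pos),
                 config = config),
            class = "synthetic_tracing")
}

#' Generate synthetic FF and FB laminar depth profiles
#'
#' Counts per depth bin are drawn as Poisson variates around two Gaussian
#' bumps on the normalized 0-100 depth axis: a lower feedforward bump and an
#' upper feedback bump, emulating the segregation of the two streams within
#' the supragranular layers.
#'
#' @param ff_center,fb_center bump centers on the depth axis (defaults 30
#'   and 70: FF below mid-depth, FB above).
#' @param bump_sd common bump standard deviation (depth units).
#' @param total expected total count per stream.
#' @param bin_width depth bin width; bins tile (0, 100).
#' @param noise \code{"poisson"} (default) or \code{"none"} (expected counts).
#' @param seed integer seed.
#' @return list with \code{ff} and \code{fb} (\code{\link{depth_profile}}
#'   objects) and \code{truth} (the bump centers).
#' @export
generate_depth_profiles <- function(ff_center = 30, fb_center = 70,
                                    bump_sd = 12, total = 500,
                                    bin_width = 5,
                                    noise = c("poisson", "none"),
                                    seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(ff_center > 0, ff_center < 100, fb_center > 0, fb_center < 100,
            bump_sd > 0, total > 0, bin_width > 0)
  centers <- seq(bin_width / 2, 100 - bin_width / 2, by = bin_width)
  intensity <- function(center) {
    f <- stats::dnorm(centers, center, bump_sd)
    total * f / sum(f)
  }
  mk <- function(center, stage) {
    lam <- intensity(center)
    cnt <- if (noise == "poisson")
      .with_stage_seed(seed, stage, stats::rpois(length(lam), lam)) else lam
    depth_profile(centers, cnt)
  }
  list(ff = mk(ff_center, 11L), fb = mk(fb_center, 12L),
       truth = list(ff_center = ff_center, fb_center = fb_center))
}
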