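test_that("incidence matrices carry -1/+1 per edge and drop the reference", {
  one <- connectivity_table(data.frame(target = "V1", source = "V2", sln = 0.7))
  inc <- build_incidence(one, "V1")
  expect_equal(unname(inc$X), matrix(-1, 1, 1))
  expect_equal(colnames(inc$X), "V2")
  expect_equal(inc$edges$source, "V2")
  expect_error(build_incidence(one, "V9"), "does not appear")

  tab <- toy_counts_table()
  inc3 <- build_incidence(tab, "V1")
  expect_equal(rowSums(inc3$X_full), rep(0, 3))
  expect_true(all(apply(inc3$X_full, 1, function(r) sum(r != 0)) == 2))
  # 3 areas, all 6 directed edges -> 6 x 2 after deletion
  full <- connectivity_table(expand.grid(
    target = c("A", "B", "C"), source = c("A", "B", "C"),
    stringsAsFactors = FALSE) |> subset(target != source) |>
      transform(sln = 0.5))
  inc6 <- build_incidence(full, "A")
  expect_equal(dim(inc6$X), c(6, 2))
})

test_that("beta-binomial pmf normalizes and reaches the binomial limit", {
  for (n in c(1, 5, 12, 15)) for (mu in c(0.1, 0.3, 0.5, 0.9))
    for (phi in c(0.01, 0.2, 0.6, 0.9)) {
      expect_equal(sum(exp(betabin_logpmf(0:n, n, mu, phi))), 1,
                   tolerance = 1e-10,
                   label = sprintf("normalization n=%d mu=%g phi=%g", n, mu, phi))
    }
  k <- 0:10
  for (mu in c(0.05, 0.3, 0.7))
    expect_equal(betabin_logpmf(k, 10, mu, 0), dbinom(k, 10, mu, log = TRUE),
                 tolerance = 1e-12)
  # continuity: small phi approaches the binomial
  expect_lt(max(abs(betabin_logpmf(k, 10, 0.3, 1e-9) -
                      dbinom(k, 10, 0.3, log = TRUE))), 1e-6)
  expect_error(betabin_logpmf(3, 10, 1.2, 0.1), "mu")
  expect_error(betabin_logpmf(3, 10, 0.5, 1), "phi")
  expect_error(betabin_logpmf(11, 10, 0.5, 0.1), "k")
})

test_that("beta-binomial draws reproduce the printed variance formula", {
  set.seed(33)
  n <- 20; mu <- 0.4; phi <- 0.15; N <- 20000
  prop <- rbetabinom(N, n, mu, phi) / n
  v_hat <- var(prop)
  v_theory <- (1 / n) * mu * (1 - mu) * (1 + (n - 1) * phi)
  se_v <- sqrt((mean((prop - mean(prop))^4) - v_hat^2) / N)
  expect_lt(abs(v_hat - v_theory), 3 * se_v)
})

test_that("hierarchy levels are recovered from synthetic laminar counts", {
  # 8 areas on a known ladder, 40 random edges, high counts, low dispersion
  set.seed(95)
  p <- 8; levels_true <- (0:7) * 0.35
  pairs <- expand.grid(s = 1:p, t = 1:p)
  pairs <- pairs[pairs$s != pairs$t, ]
  pairs <- pairs[sample.int(nrow(pairs), 40), ]
  mu <- pnorm(levels_true[pairs$t] - levels_true[pairs$s])
  k <- rbetabinom(40, 1000, pmin(pmax(mu, 1e-6), 1 - 1e-6), 0.05)
  areas <- sprintf("A%d", 1:p)
  tab <- connectivity_table(data.frame(
    target = areas[pairs$t], source = areas[pairs$s],
    supra = k, infra = 1000L - k))
  inc <- build_incidence(tab, "A1")
  fit <- fit_hierarchy_betabin(tab$supra, tab$supra + tab$infra, inc)
  expect_true(fit$converged)
  est <- fit$levels_raw[areas]
  expect_gte(cor(levels_true, est), 0.99)
  expect_equal(unname(fit$levels_raw["A1"]), 0)
  expect_equal(unname(fit$se_raw["A1"]), 0)
})

test_that("the reference area reports level 1 with zero width after rescaling", {
  cfg <- synthetic_config(n_areas = 6, seed = 7)
  sim <- simulate_tracing(cfg)
  fit <- fit_hierarchy(sim$table, drop_area = "A01", rescale = c(1, 10))
  expect_equal(unname(fit$se["A01"]), 0)
  expect_equal(sort(unname(range(fit$levels))), c(1, 10))
})

test_that("a balanced single edge implies zero hierarchical distance", {
  tab <- connectivity_table(data.frame(
    target = "B", source = "A", supra = 50L, infra = 50L))
  inc <- build_incidence(tab, "A")
  fit <- fit_hierarchy_betabin(50L, 100L, inc)
  expect_equal(unname(fit$levels_raw["B"]), 0, tolerance = 1e-3)
})

test_that("disconnected graphs are refused, naming the stranded component", {
  tab <- connectivity_table(data.frame(
    target = c("A", "C"), source = c("B", "D"),
    supra = c(10L, 10L), infra = c(10L, 10L)))
  inc <- build_incidence(tab, "A")
  expect_error(fit_hierarchy_betabin(tab$supra, tab$supra + tab$infra, inc),
               "disconnected")
  # the high-level wrapper drops the stranded areas with a warning instead
  expect_warning(fit <- fit_hierarchy(tab, drop_area = "A", rescale = NULL),
                 "not connected")
  expect_setequal(names(fit$levels), c("A", "B"))
})

test_that("the identity-link fit equals the normal-equations solution", {
  chain <- connectivity_table(data.frame(
    target = c("B", "C"), source = c("A", "B"), sln = c(0.8, 0.8)))
  incc <- build_incidence(chain, "A")
  fitc <- fit_hierarchy_linear(chain$sln, incc)
  expect_equal(unname(fitc$levels_raw[c("A", "B", "C")]), c(0, 0.8, 1.6),
               tolerance = 1e-12)
  single <- connectivity_table(data.frame(target = "B", source = "A", sln = 0.9))
  fits <- fit_hierarchy_linear(0.9, build_incidence(single, "A"))
  expect_equal(unname(fits$levels_raw["B"]), 0.9)

  cfg <- synthetic_config(n_areas = 9, seed = 17)
  sim <- simulate_tracing(cfg)
  inc <- build_incidence(sim$table, "A01")
  y <- sim$table$sln
  fit <- fit_hierarchy_linear(y, inc)
  # brute-force normal equations as the independent oracle
  X <- inc$X
  beta_ne <- solve(t(X) %*% X, t(X) %*% y)[, 1]
  rss_ne <- sum((y - X %*% beta_ne)^2)
  expect_equal(unname(fit$levels_raw[colnames(X)]), unname(beta_ne),
               tolerance = 1e-10)
  expect_equal(fit$rss, rss_ne, tolerance = 1e-10)
})

test_that("predictions follow the link and ignore reporting rescale", {
  tab <- toy_counts_table()
  inc <- build_incidence(tab, "V1")
  # all levels zero: probit link predicts 0.5 everywhere
  fitp <- fit_hierarchy_betabin(tab$supra, tab$supra + tab$infra, inc)
  fitp$levels_raw[] <- 0
  expect_equal(predict_sln(fitp, inc), rep(0.5, 3))
  # a single edge with level difference qnorm(0.95) predicts SLN 0.95
  one <- connectivity_table(data.frame(target = "B", source = "A", sln = 0.5))
  inco <- build_incidence(one, "A")
  f1 <- fit_hierarchy_betabin(50L, 100L, inco)
  f1$levels_raw["B"] <- qnorm(0.95)
  expect_equal(predict_sln(f1, inco), 0.95, tolerance = 1e-12)
  # identity-link predictions clip to [0, 1]
  f2 <- fit_hierarchy_linear(0.5, inco)
  f2$levels_raw["B"] <- 1.2
  expect_equal(predict_sln(f2, inco), 1)
  # rescaling leaves predictions unchanged
  cfg <- synthetic_config(n_areas = 6, seed = 3)
  sim <- simulate_tracing(cfg)
  inc6 <- build_incidence(sim$table, "A01")
  fit6 <- fit_hierarchy_linear(sim$table$sln, inc6)
  expect_equal(predict_sln(rescale_levels(fit6, 1, 10), inc6),
               predict_sln(fit6, inc6))
})

test_that("rescaling maps the level range affinely and is idempotent", {
  tab <- connectivity_table(data.frame(
    target = c("B", "C"), source = c("A", "B"), sln = c(0.9, 0.9)))
  inc <- build_incidence(tab, "A")
  fit <- fit_hierarchy_linear(tab$sln, inc)
  fit$levels_raw <- c(A = 0, B = 1.5, C = 3); fit$se_raw <- c(A = 0, B = 0.2, C = 0.3)
  r1 <- rescale_levels(fit, 1, 10)
  expect_equal(unname(r1$levels), c(1, 5.5, 10))
  expect_equal(unname(r1$se), c(0, 0.2, 0.3) * 3)
  expect_equal(rescale_levels(r1, 1, 10)$levels, r1$levels)
  flat <- fit; flat$levels_raw <- c(A = 1, B = 1, C = 1)
  expect_error(rescale_levels(flat), "equal")
})

test_that("translation of true levels leaves generated data and fits unchanged", {
  base <- synthetic_config(n_areas = 6, true_levels = c(0, .4, .8, 1.2, 1.6, 2),
                           seed = 29)
  shift <- synthetic_config(n_areas = 6, true_levels = c(0, .4, .8, 1.2, 1.6, 2) + 5,
                            seed = 29)
  a <- simulate_tracing(base); b <- simulate_tracing(shift)
  expect_identical(as.data.frame(a$table), as.data.frame(b$table))
  fa <- fit_hierarchy(a$table, drop_area = "A01", rescale = NULL)
  fb <- fit_hierarchy(b$table, drop_area = "A01", rescale = NULL)
  expect_equal(fa$levels_raw, fb$levels_raw)
})

test_that("model comparison is seeded, symmetric at equality, and favors the generator", {
  cfg <- synthetic_config(n_areas = 6, phi = 0.08, counts_per_edge = 2000,
                          edge_density = 0.95, level_span = 2, seed = 5001)
  sim <- simulate_tracing(cfg); tab <- sim$table
  inc <- build_incidence(tab, "A01")
  y <- tab$sln
  fb <- fit_hierarchy_betabin(tab$supra, tab$supra + tab$infra, inc)
  fl <- fit_hierarchy_linear(y, inc)
  same <- compare_models(y, fb, fb, inc, B = 200, seed = 1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  c1 <- compare_models(y, fb, fl, inc, B = 500, seed = 9)
  c2 <- compare_models(y, fb, fl, inc, B = 500, seed = 9)
  expect_identical(c1$statistic, c2$statistic)
  expect_error(compare_models(y[1:5], fb, fl, inc), "10 edges")
  # probit-generated data favor the beta-binomial model almost always
  fav <- 0
  for (s in 1:10) {
    cfg <- synthetic_config(n_areas = 6, phi = 0.08, counts_per_edge = 2000,
                            edge_density = 0.95, level_span = 2, seed = 5100 + s)
    sim <- simulate_tracing(cfg); tab <- sim$table
    inc <- build_incidence(tab, "A01")
    fb <- fit_hierarchy_betabin(tab$supra, tab$supra + tab$infra, inc)
    fl <- fit_hierarchy_linear(tab$sln, inc)
    fav <- fav + (compare_models(tab$sln, fb, fl, inc, B = 300, seed = s)$statistic > 0)
  }
  expect_gte(fav, 9)
})

test_that("SLN-only tables are fitted through synthesized counts and flagged", {
  t2 <- load_table2()
  fit <- fit_hierarchy(t2, model = "betabin", drop_area = "V1",
                       sources = area_set("fve"),
                       targets = area_set("targets11"),
                       n_eff = 50)
  expect_true(fit$approximate)
  expect_equal(fit$n_eff, 50)
  expect_equal(unname(fit$levels["V1"]), 1)  # reference at the bottom scale end or fixed
  expect_equal(sort(unname(range(fit$levels))), c(1, 10))
  # higher-order areas sit above the early ones on the rescaled ladder
  expect_gt(fit$levels["7A"], fit$levels["V2"])
})

test_that("ML estimates agree with an independent beta-binomial fitter", {
  cfg <- synthetic_config(n_areas = 8, phi = 0.1, counts_per_edge = 200, seed = 64)
  sim <- simulate_tracing(cfg); tab <- sim$table
  inc <- build_incidence(tab, "A01")
  k <- tab$supra; n <- tab$supra + tab$infra
  fit <- fit_hierarchy_betabin(k, n, inc)
  dat <- as.data.frame(inc$X); dat$k <- k; dat$nk <- n - k
  form <- stats::as.formula(paste("cbind(k, nk) ~ 0 +",
    paste(sprintf("`%s`", colnames(inc$X)), collapse = "+")))
  m <- suppressWarnings(glmmTMB::glmmTMB(
    form, family = glmmTMB::betabinomial(link = "probit"), data = dat))
  expect_equal(unname(fit$levels_raw[colnames(inc$X)]),
               unname(glmmTMB::fixef(m)$cond), tolerance = 1e-3)
  expect_equal(fit$phi, 1 / (1 + glmmTMB::sigma(m)), tolerance = 1e-2)
})
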