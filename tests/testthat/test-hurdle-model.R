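# Hurdle-exponential likelihood, sampler, diagnostics and derived decisions.

make_params <- function(p, mu, b_boat = NULL, b_net = NULL) {
  list(p = p, mu = mu, b_boat = b_boat, b_net = b_net)
}

test_that("hurdle log-likelihood matches hand values and a brute-force sum", {
  d0 <- hurdle_data(x = 0, type = "PMF", boat = "B1", net = "N1")
  expect_equal(hurdle_loglik(make_params(c(PMF = 0.4), c(PMF = 1)), d0),
               log(0.6))
  d1 <- hurdle_data(x = 2, type = "PMF", boat = "B1", net = "N1")
  expect_equal(hurdle_loglik(make_params(c(PMF = 0.4), c(PMF = 2)), d1),
               log(0.4) + log(0.5) - 1)

  # 20-wall toy set vs independent term-by-term summation
  set.seed(42)
  n <- 20
  type <- sample(c("PMF", "MMF"), n, TRUE)
  boat <- sample(c("B1", "B2"), n, TRUE)
  net <- paste0(boat, "_N", sample(1:3, n, TRUE))
  x <- ifelse(runif(n) < 0.5, 0, rexp(n, 1 / 2))
  d <- hurdle_data(x, type, boat, net)
  p <- c(PMF = 0.45, MMF = 0.55)
  mu <- c(PMF = 2.2, MMF = 1.8)
  bb <- c(B1 = 0.1, B2 = -0.2)
  bn <- setNames(runif(length(unique(net)), -0.3, 0.3), unique(net))
  oracle <- 0
  for (i in seq_len(n)) {
    w <- as.integer(x[i] > 0)
    oracle <- oracle + log(ifelse(w == 1, p[type[i]], 1 - p[type[i]]))
    if (w == 1) {
      m <- mu[type[i]] + bb[boat[i]] + bn[net[i]]
      oracle <- oracle + log(1 / m) - x[i] / m
    }
  }
  expect_equal(hurdle_loglik(make_params(p, mu, bb, bn), d),
               as.numeric(oracle))

  # nonpositive mean on an occupied wall signals invalid parameters
  expect_identical(hurdle_loglik(make_params(c(PMF = 0.4), c(PMF = -1)), d1),
                   -Inf)
})

test_that("likelihood is unimodal in the wall mean around the observation", {
  d <- hurdle_data(x = 3, type = "A", boat = "B1", net = "N1")
  ll <- function(m) hurdle_loglik(make_params(c(A = 0.5), c(A = m)), d)
  ms <- seq(0.5, 12, by = 0.25)
  lls <- vapply(ms, ll, numeric(1))
  peak <- which.max(lls)
  expect_equal(ms[peak], 3)  # exponential loglik peaks at m = x
  expect_true(all(diff(lls[1:peak]) > 0))
  expect_true(all(diff(lls[peak:length(lls)]) < 0))
})

test_that("Gelman-Rubin statistic matches hand evaluation of the formula", {
  expect_equal(gelman_rubin(list(c(1, 2, 3), c(1, 2, 3))), sqrt(2 / 3))
  expect_equal(gelman_rubin(list(c(1, 2, 3), c(101, 102, 103))),
               sqrt((2 / 3 + 15000 / 3) / 1))
  # two halves of one long well-mixed run converge
  set.seed(7)
  z <- rnorm(4000)
  expect_lt(gelman_rubin(list(z[1:2000], z[2001:4000])), 1.1)
  expect_warning(r <- gelman_rubin(list(c(1, 1), c(1, 1))), "zero")
  expect_true(is.nan(r))
  expect_error(gelman_rubin(list(1:3)), "2 chains")
})

test_that("sampler is reproducible and matches the conjugate submodel", {
  sim <- small_sim(seed = 21)
  items <- process_items(sim$items, sim$lw, sim$prices)
  hd <- wall_response(sim$walls, items, "discard_kg")
  ctl <- hurdle_control("fast", retained = 600, burn_in = 200)
  f1 <- fit_hurdle(hd, ctl, seed = 3)
  f2 <- fit_hurdle(hd, ctl, seed = 3)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_hurdle(hd, ctl, seed = 4)
  expect_false(identical(f1$draws, f3$draws))

  # with the flat prior the p draws are exactly Beta(1 + S, 1 + F)
  s <- sum(hd$w[hd$type == "PMF"])
  f <- sum(hd$type == "PMF") - s
  ks <- suppressWarnings(
    stats::ks.test(posterior_draws(f1, "p[PMF]"), stats::pbeta,
                   shape1 = 1 + s, shape2 = 1 + f))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("degenerate fit recovers known occurrence and mean", {
  # sigma fixed at 0, single gear type, n = 2000, p = 0.5, mu = 1.3
  set.seed(10)
  n <- 2000
  w <- rbinom(n, 1, 0.5)
  x <- ifelse(w == 1, rexp(n, 1 / 1.3), 0)
  d <- hurdle_data(x, rep("PMF", n), rep("B1", n), rep("N1", n))
  fit <- fit_hurdle(d, hurdle_control("fast", fix_sigma_boat = 0,
                                      fix_sigma_net = 0), seed = 8)
  s <- summary(fit)
  p_row <- s[s$parameter == "p[PMF]", ]
  mu_row <- s[s$parameter == "mu[PMF]", ]
  expect_lt(abs(p_row$mean - 0.5), 3 * p_row$sd)
  expect_lt(abs(mu_row$mean - 1.3), 3 * mu_row$sd)
  # fixed scales stay put and are flagged NA in the diagnostic column
  expect_equal(unique(as.numeric(fit$draws[, "sigma_boat", ])), 0)
  expect_true(is.na(s$rhat[s$parameter == "sigma_boat"]))
})

test_that("net expectation combines occurrence and mean per draw", {
  e1 <- net_expectation(0.5, mu = 2, n_walls = 22)
  expect_equal(e1$mean, 22)
  expect_equal(net_expectation(rep(0, 50), mu = rexp(50))$mean, 0)
  e2 <- net_expectation(c(0.3, 0.5), mu = c(40, 40))
  expect_equal(e2$draws, c(264, 440))
  expect_equal(e2$mean, 352)
  # linear in n_walls
  e3 <- net_expectation(c(0.3, 0.5), mu = c(40, 40), n_walls = 44)
  expect_equal(e3$draws, 2 * e2$draws)

  sim <- small_sim(seed = 31)
  items <- process_items(sim$items, sim$lw, sim$prices)
  fit <- fit_hurdle(wall_response(sim$walls, items, "discard_kg"),
                    hurdle_control("fast", retained = 300, burn_in = 100),
                    seed = 5)
  expect_error(net_expectation(fit, "NOT_A_TYPE"), "unknown gear type")
  e <- net_expectation(fit, "PMF")
  expect_length(e$draws, 300)
  expect_true(e$cri[1] <= e$mean && e$mean <= e$cri[2])
})

test_that("relevance labels follow the credibility interval", {
  expect_equal(relevance(rexp(500) + 0.1)$label, "RELEVANT")
  set.seed(3)
  sym <- rnorm(1000)
  expect_equal(relevance(sym)$label, "NOT_RELEVANT")
  u <- runif(1000, -1, 3)
  r <- relevance(u)
  expect_equal(r$cri_low, -0.9, tolerance = 0.08)
  expect_equal(r$cri_high, 2.9, tolerance = 0.08)
  expect_equal(r$label, "NOT_RELEVANT")
  # invariant to permutation of the draws
  r2 <- relevance(sample(u))
  expect_equal(r2$label, r$label)
  expect_equal(r2$cri_low, r$cri_low)
  expect_error(relevance(rnorm(50)), "100 draws")
  expect_error(relevance(rnorm(200), rnorm(100)), "equal length")
})

test_that("net-level comparison reproduces the least-squares decomposition", {
  r <- compare_net_level(c(0, 0.2, 1, 1.2), c("A", "A", "B", "B"))
  expect_equal(r$ss_effect, 1.0)
  expect_equal(r$ss_residual, 0.04)
  expect_equal(r$statistic, 50)
  expect_equal(r$df1, 1L)
  expect_equal(r$df2, 2L)

  same <- compare_net_level(c(1, 2, 3, 1, 2, 3), rep(c("A", "B"), each = 3))
  expect_lt(same$statistic, 1e-20)
  expect_gt(same$p_value, 0.999)

  # random data vs brute-force projection-matrix computation
  set.seed(11)
  y <- rnorm(30)
  g <- factor(sample(c("A", "B", "C"), 30, TRUE))
  X <- stats::model.matrix(~g)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  yc <- y - mean(y)
  ss_fit <- sum((H %*% y - mean(y))^2)
  ss_res <- sum((y - H %*% y)^2)
  r2 <- compare_net_level(y, g)
  expect_equal(r2$ss_effect, ss_fit, tolerance = 1e-10)
  expect_equal(r2$ss_residual, ss_res, tolerance = 1e-10)
  expect_equal(r2$statistic, (ss_fit / 2) / (ss_res / 27), tolerance = 1e-10)
  expect_error(compare_net_level(c(1, 2), c("A", "B")), "residual")
})

test_that("a fit with no positive walls for one type warns and returns prior draws", {
  set.seed(12)
  n <- 60
  type <- rep(c("PMF", "MMF"), each = n / 2)
  x <- c(rexp(n / 2, 1), rep(0, n / 2))
  d <- hurdle_data(x, type, rep("B1", n), rep(c("N1", "N2"), each = n / 2))
  expect_warning(fit <- fit_hurdle(d, hurdle_control("fast", retained = 300,
                                                     burn_in = 100),
                                   seed = 2),
                 "no positive walls")
  mu_mmf <- posterior_draws(fit, "mu[MMF]")
  # roughly uniform over (0, mu_upper): mean near the middle, wide spread
  expect_gt(stats::sd(mu_mmf), 0.2 * fit$mu_upper)
})
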