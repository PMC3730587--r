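test_that("pure-birth, no-lag cherry ages stay within the horizon", {
  d <- simulate_sister_ages(lambda = 0.5, mu = 0, phi = 0, T_sim = 4,
                            n_trees = 1000, seed = 31)
  expect_gt(d$n_ages, 0)
  expect_true(all(d$ages <= 4 + 1e-12))
  expect_true(all(d$ages >= 0))
})

test_that("a longer recognition lag shifts recognized ages older", {
  d0 <- simulate_sister_ages(0.5, 0, phi = 0, T_sim = 6, n_trees = 1500,
                             seed = 32)
  d2 <- simulate_sister_ages(0.5, 0, phi = 2, T_sim = 6, n_trees = 1500,
                             seed = 32)
  expect_gt(mean(d2$ages), mean(d0$ages))
})

test_that("mean recognized age increases monotonically in phi", {
  means <- vapply(c(0, 0.5, 1, 2), function(phi)
    mean(simulate_sister_ages(0.4, 0, phi, T_sim = 6, n_trees = 1500,
                              seed = 33)$ages), numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("higher speciation rates give younger cherry ages", {
  m_slow <- mean(simulate_sister_ages(0.3, 0, 0, T_sim = 5, n_trees = 2000,
                                      seed = 34)$ages)
  m_fast <- mean(simulate_sister_ages(1.2, 0, 0, T_sim = 5, n_trees = 2000,
                                      seed = 34)$ages)
  expect_lt(m_fast, m_slow)
})

test_that("age histogram agrees with an independently coded simulator", {
  d <- simulate_sister_ages(1, 0, 0, T_sim = 5, n_trees = 2000, seed = 35)
  set.seed(35)
  oracle_ages <- naive_bd_cherries(1, 0, 0, t_sim = 5, n_trees = 2000)
  br <- seq(0, 5, length.out = 21)
  p1 <- hist(d$ages, breaks = br, plot = FALSE)$counts / d$n_ages
  p2 <- hist(oracle_ages, breaks = br, plot = FALSE)$counts /
    length(oracle_ages)
  tv <- sum(abs(p1 - p2)) / 2
  expect_lt(tv, 0.05)
})

test_that("lag pruning matches the oracle when phi > 0", {
  d <- simulate_sister_ages(0.8, 0.2, 0.5, T_sim = 5, n_trees = 3000,
                            seed = 36)
  set.seed(36)
  oracle_ages <- naive_bd_cherries(0.8, 0.2, 0.5, t_sim = 5,
                                   n_trees = 3000)
  br <- seq(0, 5, length.out = 21)
  p1 <- hist(d$ages, breaks = br, plot = FALSE)$counts / d$n_ages
  p2 <- hist(oracle_ages, breaks = br, plot = FALSE)$counts /
    length(oracle_ages)
  expect_lt(sum(abs(p1 - p2)) / 2, 0.05)
})

test_that("the smoothed histogram is a proper floored distribution", {
  d <- simulate_sister_ages(0.5, 0.1, 0.3, T_sim = 5, n_trees = 1000,
                            seed = 37)
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)
  expect_true(all(d$prob >= d$eps - 1e-15))
  expect_equal(d$eps, 1 / (d$n_ages + d$n_bins))
})

test_that("age_log_density handles uniform, out-of-support and negative ages", {
  d <- structure(list(breaks = seq(0, 10, 1), prob = rep(0.1, 10),
                      eps = 0.005, T_sim = 10, n_bins = 10L),
                 class = "age_distribution")
  expect_equal(age_log_density(d, c(0.5, 3.7, 9.99)), rep(log(0.1), 3))
  expect_equal(age_log_density(d, 12), log(0.005))
  expect_error(age_log_density(d, -1), "non-negative")
})

test_that("constant-model log-likelihood ignores the S column", {
  set.seed(38)
  obs <- data.frame(age = runif(40, 0.2, 4), S = runif(40, 0, 2))
  p <- c(b_lambda = 0, c_lambda = 0.4, b_mu = 0, c_mu = 0, phi = 0.3)
  ll1 <- loglik_bd(obs, p, "constant", list(n_trees = 500, seed = 5))
  obs2 <- obs; obs2$S <- sample(obs2$S)
  ll2 <- loglik_bd(obs2, p, "constant", list(n_trees = 500, seed = 5))
  expect_identical(ll1, ll2)
})

test_that("common random numbers make the objective bit-identical", {
  set.seed(39)
  obs <- data.frame(age = runif(30, 0.2, 4), S = runif(30, 0, 2))
  p <- c(b_lambda = 0.05, c_lambda = 0.4, b_mu = 0.01, c_mu = 0.05,
         phi = 0.3)
  cfg <- list(n_trees = 300, G = 5, seed = 9)
  ll1 <- loglik_bd(obs, p, "linear_in_S", cfg)
  ll2 <- loglik_bd(obs, p, "linear_in_S", cfg)
  expect_identical(ll1, ll2)
})

test_that("an outlying age only loses likelihood (floor applies)", {
  set.seed(40)
  obs <- data.frame(age = runif(30, 0.2, 3), S = 0)
  p <- c(b_lambda = 0, c_lambda = 0.5, b_mu = 0, c_mu = 0, phi = 0)
  cfg <- list(n_trees = 1000, seed = 11, T_sim = 6)
  ll <- loglik_bd(obs, p, "constant", cfg)
  obs_out <- obs; obs_out$age[1] <- 50
  ll_out <- loglik_bd(obs_out, p, "constant", cfg)
  expect_true(is.finite(ll_out))
  expect_lt(ll_out, ll)
})

test_that("the true rates out-score a threefold-too-fast lambda", {
  cfg_gen <- study_config(n_pairs = 10, seed = 41,
                          bd_truth = list(b_lambda = 0, c_lambda = 0.3,
                                          b_mu = 0, c_mu = 0.1,
                                          phi = 0.5))
  ages <- gen_sister_ages(cfg_gen, n = 300)$observations
  cfg <- list(n_trees = 2000, seed = 13)
  ll_true <- loglik_bd(ages, c(b_lambda = 0, c_lambda = 0.3, b_mu = 0,
                               c_mu = 0.1, phi = 0.5), "constant", cfg)
  ll_bad <- loglik_bd(ages, c(b_lambda = 0, c_lambda = 0.9, b_mu = 0,
                              c_mu = 0.1, phi = 0.5), "constant", cfg)
  expect_gt(ll_true, ll_bad)
})

test_that("infeasible rates return -Inf rather than erroring", {
  obs <- data.frame(age = c(1, 2), S = c(0, 2))
  expect_identical(loglik_bd(obs, c(b_lambda = -0.5, c_lambda = 0.3,
                                    b_mu = 0, c_mu = 0, phi = 0),
                             "linear_in_S"), -Inf)
  expect_identical(loglik_bd(obs, c(b_lambda = 0, c_lambda = 0.3,
                                    b_mu = 0, c_mu = 0, phi = -1),
                             "constant"), -Inf)
})

test_that("constant-model fit is invariant to shuffling S", {
  set.seed(42)
  obs <- data.frame(age = runif(40, 0.3, 4), S = runif(40, 0, 2))
  cfg <- list(n_trees = 400, seed = 17)
  f1 <- fit_bd(obs, "constant", cfg, n_restarts = 1, maxit = 60)
  obs2 <- obs; obs2$S <- sample(obs2$S)
  f2 <- fit_bd(obs2, "constant", cfg, n_restarts = 1, maxit = 60)
  expect_identical(f1$params, f2$params)
})

test_that("compare_bd reports AIC arithmetic and the r(S) slope", {
  f <- function(params, logL, k, cov) structure(
    list(params = params, logL = logL, k = k, AIC = 2 * k - 2 * logL,
         covariate = cov, n = 39,
         r_slope = unname(params["b_lambda"] - params["b_mu"])),
    class = "bd_fit")
  pc <- c(b_lambda = 0, c_lambda = 0.3, b_mu = 0, c_mu = 0.1, phi = 0.3)
  pl <- c(b_lambda = 0.02, c_lambda = 0.28, b_mu = 0.006, c_mu = 0.09,
          phi = 0.3)
  fc <- f(pc, -50, 3, "constant"); fl <- f(pl, -48, 5, "linear_in_S")
  cmp <- compare_bd(fc, fl)
  expect_equal(cmp$delta_AIC, fc$AIC - fl$AIC)
  expect_equal(cmp$r_slope, 0.02 - 0.006)
  expect_equal(fc$AIC, 2 * 3 - 2 * (-50))
  same <- compare_bd(fc, fc)
  expect_equal(same$delta_AIC, 0)
  curves <- cmp$curves
  lin <- curves[curves$model == "linear_in_S", ]
  expect_equal(lin$r, lin$lambda - lin$mu)
})
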