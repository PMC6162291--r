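test_that("log prior sums marginals and rejects out-of-support points", {
  pr <- prior_spec(prior_uniform("a", 0, 10),
                   prior_normal("b", 1, 0.5),
                   prior_lognormal("c", -2, 0.3))
  expect_equal(log_prior(c(a = 5, b = 1, c = exp(-2)), pr),
               log(1 / 10) + dnorm(1, 1, 0.5, log = TRUE) +
                 dlnorm(exp(-2), -2, 0.3, log = TRUE))
  expect_identical(log_prior(c(a = 11, b = 1, c = 0.1), pr), -Inf)
  expect_identical(log_prior(c(a = 5, b = 1, c = -0.1), pr), -Inf)
  expect_error(log_prior(c(x = 1, b = 1, c = 0.1), pr), "configuration")
})

test_that("empirical priors are finite on their support and sample within it", {
  set.seed(4)
  s <- rnorm(5000, 0.3, 0.05)
  e <- prior_empirical("p", s, lower = 0, upper = 1)
  pr <- prior_spec(e)
  expect_true(is.finite(log_prior(c(p = 0.3), pr)))
  expect_true(is.finite(log_prior(c(p = 0.15), pr)))
  expect_identical(log_prior(c(p = -0.01), pr), -Inf)
  draws <- sample_prior(pr, 500)
  expect_true(all(draws >= 0 & draws <= 1))
})

test_that("truncated prior densities integrate to one over their support", {
  entries <- list(prior_normal("x", 0.1, 0.05, lower = 0, upper = 0.3),
                  prior_lognormal("x", -2, 0.5, lower = 0.05, upper = 0.5),
                  prior_uniform("x", 2, 5))
  for (e in entries) {
    pr <- prior_spec(e)
    lo <- max(e$lower, -10); hi <- min(e$upper, 10)
    xs <- seq(lo, hi, length.out = 20001)
    dens <- vapply(xs, function(x) exp(log_prior(c(x = x), pr)), 0)
    integral <- sum((dens[-1] + dens[-length(dens)]) / 2 * diff(xs))
    expect_equal(integral, 1, tolerance = 1e-3)
  }
})

test_that("the sampler recovers the conjugate-Gaussian posterior within 2%", {
  set.seed(42)
  y <- rnorm(20, 0.5, 0.2)
  m0 <- 0; s0 <- 1; sk <- 0.2
  pr <- prior_spec(prior_normal("theta", m0, s0))
  lp <- function(th) log_prior(th, pr) +
    sum(dnorm(y, th[["theta"]], sk, log = TRUE))
  post <- run_mcmc(lp, pr, list(n_iter = 1e5, burn_in = 5000, seed = 7))
  prec <- 1 / s0^2 + length(y) / sk^2
  mu <- (m0 / s0^2 + sum(y) / sk^2) / prec
  sdv <- sqrt(1 / prec)
  expect_lt(abs(mean(post$draws) - mu) / abs(mu), 0.02)
  expect_lt(abs(sd(post$draws) - sdv) / sdv, 0.02)
  expect_gt(post$diagnostics$acceptance_rate, 0.1)
  expect_true(all(is.finite(post$diagnostics$ess)))
})

test_that("a flat posterior samples its uniform prior", {
  pr <- prior_spec(prior_uniform("u", 0, 1))
  post <- run_mcmc(function(th) log_prior(th, pr), pr,
                   list(n_iter = 4e4, burn_in = 2000, seed = 3))
  expect_equal(mean(post$draws), 0.5, tolerance = 0.02)
  expect_equal(var(as.vector(post$draws)), 1 / 12, tolerance = 0.05)
  expect_true(all(post$draws >= 0 & post$draws <= 1))
})

test_that("fixed seeds give bit-identical chains; degenerate setups error", {
  pr <- prior_spec(prior_uniform("u", 0, 1))
  lp <- function(th) log_prior(th, pr)
  a <- run_mcmc(lp, pr, list(n_iter = 500, burn_in = 200, seed = 11))
  b <- run_mcmc(lp, pr, list(n_iter = 500, burn_in = 200, seed = 11))
  expect_identical(a$draws, b$draws)
  expect_error(run_mcmc(function(th) -Inf, pr,
                        list(n_iter = 10, burn_in = 10, seed = 1)),
               "unidentifiable")
})

test_that("posterior fitting self-recovers Normal and LogNormal families", {
  set.seed(2)
  s_n <- rnorm(1e5, 0.1, 0.02)
  f_n <- fit_posterior_distribution(s_n, "lam")
  expect_identical(f_n$selected, "normal")
  expect_lt(abs(f_n$mean - 0.1) / 0.1, 0.02)
  expect_lt(abs(f_n$sd - 0.02) / 0.02, 0.02)

  s_l <- rlnorm(1e5, -2.11, 0.35)
  f_l <- fit_posterior_distribution(s_l, "lvn")
  expect_identical(f_l$selected, "lognormal")
  expect_lt(abs(f_l$meanlog - (-2.11)) / 2.11, 0.03)
  expect_lt(abs(f_l$sdlog - 0.35) / 0.35, 0.03)

  expect_error(fit_posterior_distribution(rep(0.5, 200)), "degenerate")
  # negatives rule the LogNormal candidate out
  f_neg <- fit_posterior_distribution(rnorm(1000, 0, 1))
  expect_identical(f_neg$selected, "normal")
})

test_that("posterior-to-prior propagation truncates to the original support", {
  set.seed(9)
  draws <- matrix(rnorm(5000, 0.09, 0.03), ncol = 1,
                  dimnames = list(NULL, "lambda_apop"))
  post <- structure(list(draws = draws), class = "posterior_sample")
  base <- prior_spec(prior_uniform("lambda_apop", 0, 10),
                     prior_uniform("sigma", 1e-5, 20))
  pr2 <- posterior_to_prior(post, base, stage = "apoptosis")
  expect_identical(pr2[["lambda_apop"]]$source_stage, "apoptosis")
  expect_identical(pr2[["sigma"]]$family, "uniform")
  expect_identical(pr2[["lambda_apop"]]$lower, 0)
  expect_identical(pr2[["lambda_apop"]]$upper, 10)
  s <- sample_prior(prior_spec(pr2[["lambda_apop"]]), 2000)
  expect_true(all(s >= 0 & s <= 10))
  # self-consistency: fitted distribution close to the generating one
  expect_equal(pr2[["lambda_apop"]]$mean, 0.09, tolerance = 0.05)
  expect_equal(pr2[["lambda_apop"]]$sd, 0.03, tolerance = 0.05)
})

test_that("posterior samples round trip through delimited text", {
  set.seed(5)
  pr <- prior_spec(prior_uniform("u", 0, 1))
  post <- run_mcmc(function(th) log_prior(th, pr), pr,
                   list(n_iter = 200, burn_in = 100, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_posterior_csv(post, path)
  back <- read_posterior_csv(path)
  expect_equal(back$draws, post$draws, tolerance = 1e-15)
  expect_identical(back$seed, post$seed)
})
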