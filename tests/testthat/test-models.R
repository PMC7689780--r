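test_that("the seven model ids map one-to-one onto structure flags", {
  specs <- lapply(1:7, model_spec)
  key <- vapply(specs, function(s) paste(s$family, s$trend, s$variance_growth,
                                         s$family_effects), character(1))
  expect_equal(length(unique(key)), 7)
  expect_equal(model_spec(1)$parameters, c("sigma_w", "sigma"))
  expect_true(all(c("s", "nu", "k", "beta", "s_alpha", "nu_alpha") %in%
                    model_spec(7)$parameters))
  expect_error(model_spec(8), "1..7")
  expect_error(build_model(model_spec(5), make_pairs(list(0.1), t_myr = 100)),
               "at least 2")
  expect_error(build_model(model_spec(5), make_pairs(list(0.1, 0.2)),
                           priors = list(nu_lower = 1)), "finite")
})

test_that("model 1's implied pair-level distribution ignores distance", {
  pr <- make_pairs(as.list(c(-0.3, 0.1, 0.6)), t_myr = c(10, 400, 790))
  par <- list(sigma = 0.5, sigma_w = 0.3)
  ll_a <- pointwise_loglik(model_spec(1), pr, par)
  pr_shift <- make_pairs(as.list(c(-0.3, 0.1, 0.6)), t_myr = c(700, 20, 305))
  ll_b <- pointwise_loglik(model_spec(1), pr_shift, par)
  expect_equal(unname(ll_a), unname(ll_b), tolerance = 1e-12)
})

test_that("nested models coincide when the extra parameter is at its null value", {
  set.seed(21)
  pr <- make_pairs(lapply(1:10, function(i) rnorm(1 + i %% 3, 0, 0.5)),
                   var_by_pair = lapply(1:10, function(i) runif(1 + i %% 3, 0.01, 0.1)),
                   t_myr = seq(30, 780, length.out = 10))
  base <- list(sigma_w = 0.28, sigma = 0.45, beta = -0.03, k = 0)
  # 2 with beta=0 collapses to 1; 3 with k=0 collapses to 1; 4 nests both
  ll1 <- pointwise_loglik(model_spec(1), pr, base[c("sigma_w", "sigma")])
  ll2 <- pointwise_loglik(model_spec(2), pr, modifyList(base, list(beta = 0)))
  ll3 <- pointwise_loglik(model_spec(3), pr, base)
  ll4 <- pointwise_loglik(model_spec(4), pr, modifyList(base, list(beta = 0)))
  expect_equal(unname(ll2), unname(ll1), tolerance = 1e-12)
  expect_equal(unname(ll3), unname(ll1), tolerance = 1e-12)
  expect_equal(unname(ll4), unname(ll1), tolerance = 1e-12)
  # 4 at beta != 0, k=0 collapses to 2
  ll4b <- pointwise_loglik(model_spec(4), pr, base)
  ll2b <- pointwise_loglik(model_spec(2), pr, base[c("sigma_w", "sigma", "beta")])
  expect_equal(unname(ll4b), unname(ll2b), tolerance = 1e-12)
  # 6 with beta=0 collapses to 5; 7 with all alpha=0 collapses to 6
  tpar <- list(sigma_w = 0.28, s = 0.45, nu = 6, k = -0.2, beta = -0.03)
  ll5 <- pointwise_loglik(model_spec(5), pr, modifyList(tpar, list(beta = NULL)))
  ll6 <- pointwise_loglik(model_spec(6), pr, modifyList(tpar, list(beta = 0)))
  expect_equal(unname(ll6), unname(ll5), tolerance = 1e-12)
  ll6b <- pointwise_loglik(model_spec(6), pr, tpar)
  ll7 <- pointwise_loglik(model_spec(7), pr, c(tpar, list(alpha = 0)))
  expect_equal(unname(ll7), unname(ll6b), tolerance = 1e-12)
})

test_that("Student-t models approach their normal counterparts as df grows", {
  set.seed(22)
  pr <- make_pairs(lapply(1:10, function(i) rnorm(2, 0, 0.6)),
                   var_by_pair = lapply(1:10, function(i) rep(0.05, 2)),
                   t_myr = seq(40, 760, length.out = 10))
  par_n <- list(sigma_w = 0.3, sigma = 0.5, beta = -0.02, k = 0)
  par_t <- list(sigma_w = 0.3, s = 0.5, nu = 1e6, beta = -0.02, k = 0)
  ll_normal <- pointwise_loglik(model_spec(4), pr, par_n)
  ll_t <- pointwise_loglik(model_spec(6), pr, par_t)
  expect_lt(max(abs(ll_t - ll_normal)), 1e-3)
})

test_that("the collapsed pair likelihood matches brute-force quadrature over both latent layers", {
  # 3-pair fixture with unequal replicate counts and measurement variances
  r_by_pair <- list(c(0.25, -0.1), c(-0.8), c(0.4, 0.05, 0.6))
  v_by_pair <- list(c(0.03, 0.06), c(0.02), c(0.05, 0.01, 0.08))
  pr <- make_pairs(r_by_pair, v_by_pair, t_myr = c(120, 430, 700))
  cases <- list(
    list(id = 1, par = list(sigma = 0.5)),
    list(id = 2, par = list(sigma = 0.4, beta = -0.05)),
    list(id = 4, par = list(sigma = 0.35, beta = 0.03, k = 0.04)),
    list(id = 5, par = list(s = 0.3, nu = 4, k = -0.2)),
    list(id = 6, par = list(s = 0.45, nu = 8, k = -0.5, beta = -0.04))
  )
  for (cs in cases) {
    par <- c(cs$par, list(sigma_w = 0.25))
    ll <- pointwise_loglik(model_spec(cs$id), pr, par)
    for (j in 1:3) {
      oracle <- brute_pair_loglik(r_by_pair[[j]], v_by_pair[[j]],
                                  t100 = pr$pairs$t_myr[j] / 100,
                                  spec_id = cs$id, par = cs$par,
                                  sigma_w = 0.25)
      expect_equal(unname(ll[1, j]), oracle, tolerance = 1e-4,
                   label = sprintf("model %d, pair %d", cs$id, j))
    }
  }
})

test_that("unsatisfiable degrees-of-freedom configurations are refused", {
  expect_error(
    simulation_config(generating_model = 5, params = list(nu = 3, k = -0.5)),
    "exceed 2")
  expect_error(
    simulation_config(generating_model = 3, params = list(sigma = 0.2, k = -0.1)),
    "positive")
})
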