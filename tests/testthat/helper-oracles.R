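# Independent oracles used to freeze expected values ---------------------

# Monte-Carlo sampling variance of r: sample the four means from normals
# with the stated SDs and take the empirical variance of the recomputed r.
mc_r_variance <- function(A_a, B_a, A_b, B_b, se, n = 1e6, seed = 99) {
  set.seed(seed)
  aa <- rnorm(n, A_a, se[1]); ba <- rnorm(n, B_a, se[2])
  ab <- rnorm(n, A_b, se[3]); bb <- rnorm(n, B_b, se[4])
  keep <- aa > 0 & ba > 0 & ab > 0 & bb > 0
  var(log(aa[keep] / ba[keep]) - log(ab[keep] / bb[keep]))
}

# Brute-force integrated likelihood of one pair's replicate vector under
# the full hierarchy, by nested 1-D quadrature over each replicate latent
# r*_ij and the pair latent r*_j. Deliberately naive and slow.
brute_pair_loglik <- function(r_obs, v_meas, t100, spec_id, par,
                              sigma_w) {
  spec <- model_spec(spec_id)
  mu <- if (spec$trend) par$beta * t100 else 0
  pair_dens <- function(x) {
    if (spec$family == "normal") {
      v <- par$sigma^2 + (if (spec$variance_growth) par$k * t100 else 0)
      dnorm(x, mu, sqrt(v))
    } else {
      df <- par$nu + par$k * t100
      dt((x - mu) / par$s, df) / par$s
    }
  }
  # p(r_ij | r*_j) = int N(r_ij; u, v_meas) N(u; r*_j, sigma_w^2) du
  rep_lik_given_pairmean <- function(rstar_j) {
    out <- 1
    for (i in seq_along(r_obs)) {
      f <- integrate(function(u) {
        dnorm(r_obs[i], u, sqrt(v_meas[i])) * dnorm(u, rstar_j, sigma_w)
      }, lower = rstar_j - 12 * sqrt(sigma_w^2 + v_meas[i]),
         upper = rstar_j + 12 * sqrt(sigma_w^2 + v_meas[i]),
         rel.tol = 1e-10)$value
      out <- out * f
    }
    out
  }
  span <- 14 * (abs(mu) + 2)
  val <- integrate(Vectorize(function(x) rep_lik_given_pairmean(x) * pair_dens(x)),
                   lower = mu - span, upper = mu + span,
                   rel.tol = 1e-10, subdivisions = 400)$value
  log(val)
}

# Exact leave-one-pair-out predictive density by refitting without pair j
# and scoring the held-out pair against the refitted posterior.
exact_refit_loo <- function(model_id, pairs, seed = 1, chains = 2,
                            iter = 1200, burn_in = 300, adapt = 300) {
  J <- nrow(pairs$pairs)
  elpd <- numeric(J)
  for (j in seq_len(J)) {
    keep <- pairs$pairs$pair_id[-j]
    sub <- list(pairs = pairs$pairs[-j, , drop = FALSE],
                obs = pairs$obs[pairs$obs$pair_id %in% keep, , drop = FALSE])
    class(sub) <- "psf_pairs"
    fit <- suppressWarnings(fit_model(model_id, sub, chains = chains,
                                      iter = iter, burn_in = burn_in,
                                      adapt = adapt, seed = seed + j,
                                      quiet = TRUE))
    hold <- list(pairs = pairs$pairs[j, , drop = FALSE],
                 obs = pairs$obs[pairs$obs$pair_id == pairs$pairs$pair_id[j], ,
                                 drop = FALSE])
    class(hold) <- "psf_pairs"
    dm <- as.matrix(fit$draws)
    ll <- pointwise_loglik(fit$spec, hold, dm)
    elpd[j] <- log(mean(exp(ll - max(ll)))) + max(ll)
  }
  sum(elpd)
}
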