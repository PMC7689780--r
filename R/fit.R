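#' Fit a phylogenetic-signal model by MCMC
#'
#' Runs JAGS on a model built by [build_model()] (or built on the fly from a
#' model id and a `"psf_pairs"` object). Sampling is fully deterministic
#' given `seed`: each chain gets a fixed RNG kind and a seed derived from
#' `seed` and the chain index, and initial values are deterministic, so the
#' same call yields bit-identical draws.
#'
#' The default protocol mirrors common practice for these models — several
#' chains, a substantial burn-in, Gelman-Rubin convergence checks with the
#' usual 1.1 threshold — and every setting is an argument, so scaled-down
#' runs for simulation studies are one call away.
#'
#' @param object A `"psf_model"` from [build_model()], a
#'   [model_spec()], or an integer model id 1-7.
#' @param pairs A `"psf_pairs"` object; required unless `object` is already
#'   a built model.
#' @param chains Number of MCMC chains (>= 2 so convergence can be
#'   assessed). Default 3.
#' @param iter Post-burn-in iterations per chain. Default 10000.
#' @param burn_in Burn-in iterations discarded after adaptation. Default 1000.
#' @param adapt JAGS adaptation steps. Default 500.
#' @param thin Thinning interval for stored draws. Default 1.
#' @param seed Integer master seed.
#' @param method `"joint"` fits the full hierarchy in one model so
#'   measurement uncertainty propagates into every parameter;
#'   `"two_stage"` is a plug-in sensitivity variant that first estimates
#'   each pair's mean response r*_j from the measurement layer alone and
#'   then fits the pair-level model to those estimates (with their posterior
#'   SDs as fixed sampling variances).
#' @param loglik_draws Maximum number of (evenly thinned) posterior draws on
#'   which the per-pair log-likelihood matrix is evaluated for LOO.
#'   Default 1000.
#' @param priors Optional prior overrides, see [build_model()].
#' @param quiet Suppress JAGS progress output. Default TRUE.
#' @return An object of class `"psf_fit"`: the model spec, posterior draws
#'   (a [coda::mcmc.list]), per-parameter Gelman-Rubin statistics, the
#'   per-pair pointwise log-likelihood matrix, the seed and runtime. If any
#'   R-hat exceeds 1.1 a convergence warning is recorded in
#'   `$convergence_warning` and raised.
#' @export
fit_model <- function(object, pairs = NULL, chains = 3, iter = 10000,
                      burn_in = 1000, adapt = 500, thin = 1, seed = 1,
                      method = c("joint", "two_stage"),
                      loglik_draws = 1000, priors = list(), quiet = TRUE) {
  method <- match.arg(method)
  if (!inherits(object, "psf_model")) {
    if (is.null(pairs)) stop("supply 'pairs' when 'object' is not a built model",
                             call. = FALSE)
    object <- build_model(object, pairs, priors = priors)
  }
  if (chains < 2) stop("need at least 2 chains for convergence assessment",
                       call. = FALSE)
  spec <- object$spec
  t0 <- proc.time()[["elapsed"]]

  if (method == "two_stage") {
    object <- two_stage_model(object, chains = chains, iter = min(iter, 4000),
                              burn_in = burn_in, adapt = adapt, seed = seed,
                              quiet = quiet)
  }

  inits <- lapply(seq_len(chains), function(ch) {
    c(model_inits(spec, ch),
      list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = chain_seed(seed, ch)))
  })
  if (method == "two_stage") {
    inits <- lapply(inits, function(i) i[names(i) != "sigma_w"])
  }
  jm <- rjags::jags.model(textConnection(object$code), data = object$data,
                          inits = inits, n.chains = chains, n.adapt = adapt,
                          quiet = quiet)
  if (burn_in > 0) stats::update(jm, burn_in, progress.bar = "none")
  monitors <- object$monitors
  if (method == "two_stage") monitors <- setdiff(monitors, "sigma_w")
  draws <- rjags::coda.samples(jm, monitors, n.iter = iter, thin = thin,
                               progress.bar = "none")

  rhat <- gelman_rubin(draws)
  conv_warn <- NULL
  if (any(rhat > 1.1, na.rm = TRUE)) {
    bad <- names(rhat)[which(rhat > 1.1)]
    conv_warn <- sprintf(
      "Gelman-Rubin statistic exceeds 1.1 for: %s (max %.3f); chains may not have converged",
      paste(bad, collapse = ", "), max(rhat, na.rm = TRUE))
  }

  dm <- thin_draw_matrix(draws, loglik_draws)
  ll <- loglik_matrix(spec, object$pair_data, dm,
                      two_stage = method == "two_stage")

  fit <- structure(list(
    spec = spec,
    draws = draws,
    rhat = rhat,
    pointwise_loglik = ll,
    seed = as.integer(seed),
    method = method,
    pair_data = object$pair_data,
    settings = list(chains = chains, iter = iter, burn_in = burn_in,
                    adapt = adapt, thin = thin, loglik_draws = loglik_draws),
    convergence_warning = conv_warn,
    runtime = proc.time()[["elapsed"]] - t0
  ), class = "psf_fit")
  if (!is.null(conv_warn)) warning(conv_warn, call. = FALSE)
  fit
}

chain_seed <- function(seed, chain) {
  (abs(as.integer(seed)) %% 1000000L) * 1000L + as.integer(chain)
}

# Plug-in first stage: estimate each pair's latent mean response from the
# measurement layers alone (vague pair-level prior), then rebuild the model
# with those estimates as single pseudo-observations whose sampling
# variances are the stage-1 posterior variances and no within-pair term.
two_stage_model <- function(object, chains, iter, burn_in, adapt, seed, quiet) {
  pd <- object$pair_data
  code1 <- paste(
    "model {",
    "  for (n in 1:N) {",
    "    r[n] ~ dnorm(rstar[pair[n]], 1 / (v_meas[n] + sigma_w^2))",
    "  }",
    "  for (j in 1:J) { rstar[j] ~ dnorm(0, 1.0E-4) }",
    sprintf("  sigma_w ~ dunif(0, %g)", object$priors$sd_upper),
    "}", sep = "\n")
  inits <- lapply(seq_len(chains), function(ch) {
    list(sigma_w = c(0.5, 1, 0.25, 0.75)[(ch - 1L) %% 4L + 1L],
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = chain_seed(seed + 500000L, ch))
  })
  jm <- rjags::jags.model(textConnection(code1),
                          data = list(r = pd$r, v_meas = pd$v_meas,
                                      pair = pd$pair, N = pd$N, J = pd$J),
                          inits = inits, n.chains = chains, n.adapt = adapt,
                          quiet = quiet)
  stats::update(jm, burn_in, progress.bar = "none")
  s1 <- rjags::coda.samples(jm, "rstar", n.iter = iter, progress.bar = "none")
  m <- as.matrix(s1)
  est <- colMeans(m)
  v_est <- apply(m, 2, stats::var)
  ord <- order(as.integer(sub("^rstar\\[(\\d+)\\]$", "\\1", colnames(m))))
  est <- est[ord]; v_est <- v_est[ord]

  pd2 <- pd
  pd2$r <- unname(est)
  pd2$v_meas <- pmax(unname(v_est), 1e-10)
  pd2$pair <- seq_len(pd$J)
  pd2$N <- pd$J
  object$pair_data <- pd2
  object$data$r <- pd2$r
  object$data$v_meas <- pd2$v_meas
  object$data$pair <- pd2$pair
  object$data$N <- pd2$N
  # stage 2 has one pseudo-observation per pair: drop the within-pair layer
  object$code <- sub("1 / (v_meas[n] + sigma_w^2)", "1 / v_meas[n]",
                     object$code, fixed = TRUE)
  object$code <- sub(sprintf("  sigma_w ~ dunif(0, %g)\n", object$priors$sd_upper),
                     "", object$code, fixed = TRUE)
  object
}

#' @export
print.psf_fit <- function(x, ...) {
  cat(sprintf("psf_fit: model %d (%s), %s\n", x$spec$model_id,
              model_formula(x$spec), x$method))
  cat(sprintf("  %d chains x %d iterations (burn-in %d); %d pairs; %.1f s\n",
              x$settings$chains, x$settings$iter, x$settings$burn_in,
              ncol(x$pointwise_loglik), x$runtime))
  cat(sprintf("  max R-hat: %.3f%s\n", max(x$rhat, na.rm = TRUE),
              if (is.null(x$convergence_warning)) "" else "  [NOT CONVERGED]"))
  print(posterior_summary(x), digits = 3)
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Computes the Gelman-Rubin convergence statistic (R-hat) for every
#' parameter from two or more chains, comparing between- and within-chain
#' variance; values near 1 indicate the chains are sampling the same
#' distribution, and values above 1.1 are conventionally read as
#' non-convergence. Parameters that are exactly constant across all chains
#' (zero variance) are reported as 1 by convention.
#'
#' @param draws A [coda::mcmc.list], or a plain list of per-chain draw
#'   matrices with common column names.
#' @return Named numeric vector of R-hat point estimates (one per
#'   parameter), each >= 1 where defined.
#' @export
gelman_rubin <- function(draws) {
  if (!inherits(draws, "mcmc.list")) {
    if (!is.list(draws) || length(draws) < 2) {
      stop("need draws from at least 2 chains", call. = FALSE)
    }
    draws <- coda::mcmc.list(lapply(draws, function(m) coda::mcmc(as.matrix(m))))
  }
  if (coda::nchain(draws) < 2) stop("need at least 2 chains", call. = FALSE)
  if (coda::niter(draws) < 10) stop("need at least 10 draws per chain", call. = FALSE)
  all_mat <- as.matrix(draws)
  const <- apply(all_mat, 2, function(v) max(v) - min(v) == 0)
  psrf <- rep(NA_real_, ncol(all_mat))
  names(psrf) <- colnames(all_mat)
  if (any(!const)) {
    sub <- draws[, colnames(all_mat)[!const], drop = FALSE]
    gd <- coda::gelman.diag(sub, autoburnin = FALSE, multivariate = FALSE)
    psrf[colnames(all_mat)[!const]] <- gd$psrf[, 1]
  }
  psrf[const] <- 1
  psrf[!is.finite(psrf)] <- 1
  pmax(psrf, 1)
}

#' Posterior summaries of a fitted model
#'
#' Means and central 95% credible intervals (2.5%, 50%, 97.5% quantiles)
#' for every monitored parameter, together with R-hat. Trend (`beta`) and
#' divergence-rate (`k`) parameters are on the per-100-Myr distance scale
#' used by the models.
#'
#' @param result A `"psf_fit"` or a [coda::mcmc.list].
#' @return Data frame with columns `parameter`, `mean`, `sd`, `q2.5`,
#'   `median`, `q97.5` and (for fits) `rhat`.
#' @export
posterior_summary <- function(result) {
  if (inherits(result, "psf_fit")) {
    m <- as.matrix(result$draws)
    rhat <- result$rhat[colnames(m)]
  } else {
    m <- as.matrix(result)
    rhat <- rep(NA_real_, ncol(m))
  }
  qs <- t(apply(m, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
                names = FALSE))
  out <- data.frame(
    parameter = colnames(m),
    mean = colMeans(m),
    sd = apply(m, 2, stats::sd),
    q2.5 = qs[, 1], median = qs[, 2], q97.5 = qs[, 3],
    rhat = unname(rhat),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

# Evenly thin the pooled posterior to at most max_draws rows (per-chain
# interleaving preserved deterministically).
thin_draw_matrix <- function(draws, max_draws) {
  m <- as.matrix(draws)
  if (nrow(m) > max_draws) {
    keep <- unique(round(seq(1, nrow(m), length.out = max_draws)))
    m <- m[keep, , drop = FALSE]
  }
  m
}
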