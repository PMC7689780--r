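#' Configuration for the synthetic feedback-compilation generator
#'
#' Defaults emulate the structure of the published whole-soil feedback
#' compilation: 470 unique species pairs drawn from 165 species in 39
#' families, 1-11 replicate feedbacks per pair with a mean near
#' 968/470 (about 2.06, via a geometric replicate-count distribution
#' truncated at 11), phylogenetic distances spanning 0-800 Myr with
#' within-family pairs below 300 Myr and between-family pairs above it,
#' and per-replicate measurement noise whose delta-method standard
#' deviation is around 0.2.
#'
#' The default generating model is the heavy-tailed trend model (model 6)
#' with `beta = -0.0217` per 100 Myr (a decline in mean response of about
#' 0.13 over 600 Myr), scale `s = 0.35`, baseline kurtosis `nu = 5` and
#' kurtosis-change rate `k = -0.25` per 100 Myr, within-pair variance
#' `sigma2_w = 0.1` — a regime with a clear divergent, heavy-tailed
#' signal and a slight negative trend.
#'
#' @param n_pairs Number of unique species pairs.
#' @param n_species,n_families Species pool size and family count.
#' @param generating_model [model_spec()] or integer id of the generative
#'   model.
#' @param params Named list of true parameter values for the generating
#'   model; entries among `beta`, `sigma`, `k`, `s`, `nu`, `s_alpha`,
#'   `nu_alpha` (unused ones ignored). Missing entries take the defaults
#'   above.
#' @param sigma2_w Within-pair variance of replicate latents.
#' @param replicate_prob Success probability of the truncated geometric
#'   replicate-count distribution (support 1-11). Default 0.485 gives mean
#'   about 2.06.
#' @param max_replicates Upper truncation for replicates per pair.
#' @param within_family_range,between_family_range Distance ranges (Myr)
#'   for within- and between-family species pairs.
#' @param measurement_se_meanlog,measurement_se_sdlog Lognormal parameters
#'   of the per-replicate measurement SD of r (`sigma_rij`).
#' @param biomass_baseline Baseline biomass used when emitting the four
#'   means.
#' @param seed Integer seed; the whole simulation is deterministic in it.
#' @return List of class `"psf_sim_config"`.
#' @export
simulation_config <- function(n_pairs = 470, n_species = 165, n_families = 39,
                              generating_model = 6,
                              params = list(),
                              sigma2_w = 0.1,
                              replicate_prob = 0.485, max_replicates = 11,
                              within_family_range = c(5, 300),
                              between_family_range = c(300, 800),
                              measurement_se_meanlog = log(0.2),
                              measurement_se_sdlog = 0.4,
                              biomass_baseline = 10,
                              seed = 1) {
  if (!inherits(generating_model, "psf_model_spec")) {
    generating_model <- model_spec(generating_model)
  }
  defaults <- list(beta = -0.0217, sigma = 0.35, k = NULL,
                   s = 0.35, nu = 5, s_alpha = 0.3, nu_alpha = 5)
  defaults$k <- if (generating_model$family == "normal") 0.05 else -0.25
  params <- utils::modifyList(defaults, params)
  cfg <- list(n_pairs = n_pairs, n_species = n_species,
              n_families = n_families,
              generating_model = generating_model, params = params,
              sigma2_w = sigma2_w, replicate_prob = replicate_prob,
              max_replicates = max_replicates,
              within_family_range = within_family_range,
              between_family_range = between_family_range,
              measurement_se_meanlog = measurement_se_meanlog,
              measurement_se_sdlog = measurement_se_sdlog,
              biomass_baseline = biomass_baseline,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "psf_sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_pairs >= 1, cfg$n_species >= 2, cfg$n_families >= 1,
            cfg$sigma2_w >= 0, cfg$biomass_baseline > 0,
            cfg$replicate_prob > 0, cfg$replicate_prob <= 1)
  if (cfg$n_pairs > choose(cfg$n_species, 2)) {
    stop("n_pairs exceeds the number of distinct species pairs", call. = FALSE)
  }
  gm <- cfg$generating_model
  if (gm$family == "student_t") {
    tmax100 <- max(cfg$between_family_range, cfg$within_family_range) / 100
    df_min <- cfg$params$nu + min(0, cfg$params$k) * tmax100
    if (df_min <= 2) {
      stop(sprintf(
        "degrees of freedom nu + k*t = %.2f at the maximum distance: must exceed 2 for a finite variance",
        df_min), call. = FALSE)
    }
  } else if (gm$variance_growth) {
    tmax100 <- max(cfg$between_family_range, cfg$within_family_range) / 100
    if (cfg$params$sigma^2 + min(0, cfg$params$k) * tmax100 <= 0) {
      stop("sigma^2 + k*t must stay positive at the maximum distance",
           call. = FALSE)
    }
  }
  invisible(cfg)
}

#' Simulate a synthetic feedback compilation with known truth
#'
#' Draws species pairs, phylogenetic distances and family structure, then
#' generates pair-level mean responses r*_j from the configured generating
#' model, replicate latents r*_ij ~ Normal(r*_j, sigma2_w), and observed
#' responses r_ij = r*_ij + Normal(0, sigma2_rij) measurement noise.
#' Each observation is emitted as a full four-biomass pairwise experiment:
#' species B's biomasses and species A's heterospecific biomass are fixed
#' at the baseline, species A's conspecific biomass carries the signal
#' (`A_a = baseline * exp(r_ij)`), and the four standard errors are set to
#' `mean * sigma_rij / 2` so the delta-method variance reproduces
#' sigma2_rij exactly. [compute_r()] on the emitted table therefore
#' recovers every r_ij to machine precision — the emission is one exact
#' inverse of the dissimilarity formula, chosen canonically among many.
#'
#' @param config A [simulation_config()].
#' @return List with elements `table` (a `"psf_compilation"`) and `truth`
#'   (generating parameters, per-pair `rstar_j`, per-replicate `rstar_ij`
#'   and `sigma2_rij`, family effects `alpha` where applicable, and the
#'   seed).
#' @export
simulate_pairs <- function(config) {
  stopifnot(inherits(config, "psf_sim_config"))
  validate_sim_config(config)
  gm <- config$generating_model
  p <- config$params
  withr_seed(config$seed, {
    # species -> family assignment: at least one species per family, rest random
    fam_of <- c(seq_len(config$n_families),
                sample.int(config$n_families,
                           config$n_species - config$n_families, replace = TRUE))
    fam_of <- fam_of[sample.int(config$n_species)]
    species <- sprintf("sp%03d", seq_len(config$n_species))
    families <- sprintf("fam%02d", fam_of)

    # distinct unordered species pairs
    all_pairs <- utils::combn(config$n_species, 2)
    pick <- sample.int(ncol(all_pairs), config$n_pairs)
    ia <- all_pairs[1, pick]
    ib <- all_pairs[2, pick]
    same_fam <- fam_of[ia] == fam_of[ib]
    t_myr <- ifelse(same_fam,
                    stats::runif(config$n_pairs, config$within_family_range[1],
                                 config$within_family_range[2]),
                    stats::runif(config$n_pairs, config$between_family_range[1],
                                 config$between_family_range[2]))
    t100 <- t_myr / 100

    # family-pair effects (model 7 only)
    fam_pair <- paste(pmin(families[ia], families[ib]),
                      pmax(families[ia], families[ib]), sep = "--")
    fam_levels <- sort(unique(fam_pair))
    alpha <- if (gm$family_effects) {
      p$s_alpha * stats::rt(length(fam_levels), p$nu_alpha)
    } else {
      rep(0, length(fam_levels))
    }
    names(alpha) <- fam_levels

    mu_j <- (if (gm$trend) p$beta * t100 else 0) + unname(alpha[fam_pair])
    rstar_j <- if (gm$family == "normal") {
      v <- p$sigma^2 + (if (gm$variance_growth) p$k * t100 else 0)
      stats::rnorm(config$n_pairs, mu_j, sqrt(v))
    } else {
      df <- p$nu + p$k * t100
      mu_j + p$s * stats::rt(config$n_pairs, df)
    }

    n_rep <- pmin(1L + stats::rgeom(config$n_pairs, config$replicate_prob),
                  config$max_replicates)
    pidx <- rep(seq_len(config$n_pairs), n_rep)
    N <- length(pidx)
    rstar_ij <- stats::rnorm(N, rstar_j[pidx], sqrt(config$sigma2_w))
    sigma_rij <- stats::rlnorm(N, config$measurement_se_meanlog,
                               config$measurement_se_sdlog)
    r_ij <- rstar_ij + stats::rnorm(N, 0, sigma_rij)

    base <- config$biomass_baseline
    table <- data.frame(
      study_id = sprintf("study%03d", pidx %% 50L + 1L),
      species_a = species[ia][pidx], species_b = species[ib][pidx],
      family_a = families[ia][pidx], family_b = families[ib][pidx],
      A_a = base * exp(r_ij), A_b = base, B_a = base, B_b = base,
      se_A_a = base * exp(r_ij) * sigma_rij / 2,
      se_A_b = base * sigma_rij / 2,
      se_B_a = base * sigma_rij / 2,
      se_B_b = base * sigma_rij / 2,
      phylo_distance_myr = t_myr[pidx],
      whole_soil = TRUE,
      soil_fraction = 1,
      treatment = sprintf("rep%d", stats::ave(pidx, pidx, FUN = seq_along)),
      glasshouse = TRUE,
      ecosystem = "grassland",
      origin_a = "native", origin_b = "native",
      functional_group_a = "forb", functional_group_b = "forb",
      stringsAsFactors = FALSE
    )
    class(table) <- c("psf_compilation", "feedback_experiment", "data.frame")
    truth <- list(
      model = gm, params = p, sigma2_w = config$sigma2_w,
      pair = data.frame(species_a = species[ia], species_b = species[ib],
                        family_pair = fam_pair, t_myr = t_myr,
                        rstar_j = rstar_j, n_rep = n_rep,
                        stringsAsFactors = FALSE),
      rstar_ij = rstar_ij, r_ij = r_ij, sigma2_rij = sigma_rij^2,
      alpha = alpha, seed = config$seed
    )
    list(table = table, truth = truth)
  })
}

# evaluate expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Brownian trait divergence on a simulated Yule tree
#'
#' An independent, tree-based route to the variance-growth expectation the
#' distance-based generator encodes: simulates a pure-birth (Yule)
#' phylogeny, evolves a continuous trait along its branches by Brownian
#' motion with rate `sigma_bm` (so trait differences between two tips are
#' normal with variance `sigma_bm^2` times their patristic distance), and
#' returns the pairwise distance matrix and tip trait values.
#'
#' @param n_species Number of tips (>= 3).
#' @param birth_rate Speciation rate of the Yule process.
#' @param sigma_bm Brownian rate (trait SD per unit branch length).
#' @param seed Integer seed.
#' @return List with `tree` (an [ape::phylo]), `distances` (tip-pairwise
#'   patristic distance matrix) and `traits` (named vector of tip values).
#' @export
simulate_tree_bm <- function(n_species, birth_rate = 1, sigma_bm = 1, seed = 1) {
  stopifnot(n_species >= 3, birth_rate > 0, sigma_bm >= 0)
  withr_seed(seed, {
    tree <- ape::rphylo(n_species, birth = birth_rate, death = 0)
    traits <- if (sigma_bm == 0) {
      stats::setNames(rep(0, n_species), tree$tip.label)
    } else {
      phytools::fastBM(tree, sig2 = sigma_bm^2)
    }
    list(tree = tree,
         distances = stats::cophenetic(tree),
         traits = traits)
  })
}

#' Write a synthetic compilation to CSV
#'
#' Emits the table in the package dialect (with the seed recorded in a
#' comment header) such that [read_compilation()] round-trips it
#' losslessly; a fixed seed yields a byte-identical file.
#'
#' @param sim Result of [simulate_pairs()], or a `"psf_compilation"`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
emit_compilation_csv <- function(sim, path) {
  if (is.list(sim) && !is.data.frame(sim) && !is.null(sim$table)) {
    write_compilation(sim$table, path, seed = sim$truth$seed)
  } else {
    write_compilation(sim, path)
  }
  invisible(path)
}
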