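# Build a psf_pairs object directly from pair-level quantities -----------

make_pairs <- function(r_by_pair, var_by_pair = NULL, t_myr = NULL,
                       family_pair = NULL) {
  J <- length(r_by_pair)
  if (is.null(t_myr)) t_myr <- seq(50, 750, length.out = J)
  if (is.null(var_by_pair)) var_by_pair <- lapply(r_by_pair, function(r) rep(0.04, length(r)))
  if (is.null(family_pair)) family_pair <- rep("famA--famA", J)
  pair_id <- sprintf("p%02d||q%02d", seq_len(J), seq_len(J))
  pairs <- data.frame(
    pair_id = pair_id,
    species_a = sprintf("p%02d", seq_len(J)), species_b = sprintf("q%02d", seq_len(J)),
    family_a = sub("--.*", "", family_pair), family_b = sub(".*--", "", family_pair),
    family_pair = family_pair, t_myr = t_myr,
    n_obs = lengths(r_by_pair), stringsAsFactors = FALSE)
  obs <- do.call(rbind, lapply(seq_len(J), function(j) {
    data.frame(pair_id = pair_id[j], replicate = seq_along(r_by_pair[[j]]),
               r = r_by_pair[[j]], var_r = var_by_pair[[j]], t_myr = t_myr[j],
               stringsAsFactors = FALSE)
  }))
  structure(list(pairs = pairs, obs = obs), class = "psf_pairs")
}

# small deterministic compilation data frame in the package dialect ------

make_compilation_df <- function(n = 10, whole_soil = TRUE, seed = 42) {
  set.seed(seed)
  sp <- sprintf("sp%02d", 1:8)
  ia <- sample(1:7, n, replace = TRUE)
  ib <- ia + sample(1:(8 - max(ia)), n, replace = TRUE)
  base <- runif(n, 5, 15)
  df <- data.frame(
    study_id = "s1",
    species_a = sp[ia], species_b = sp[ib],
    family_a = c("famA", "famB")[(ia %% 2) + 1],
    family_b = c("famA", "famB")[(ib %% 2) + 1],
    A_a = base * exp(rnorm(n, 0, 0.3)), A_b = base,
    B_a = base * 0.9, B_b = base * 1.1,
    se_A_a = base * 0.05, se_A_b = base * 0.05,
    se_B_a = base * 0.05, se_B_b = base * 0.05,
    phylo_distance_myr = 100 * (ia + ib),
    whole_soil = rep_len(whole_soil, n),
    soil_fraction = 1, treatment = "ctrl", glasshouse = TRUE,
    ecosystem = "grassland", origin_a = "native", origin_b = "native",
    functional_group_a = "forb", functional_group_b = "grass",
    stringsAsFactors = FALSE)
  df
}

write_fixture_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

# default scaled-down MCMC settings for unit tests
fast_fit <- function(model, pairs, seed = 1, chains = 2, iter = 800,
                     burn_in = 300, adapt = 300, ...) {
  suppressWarnings(fit_model(model, pairs, chains = chains, iter = iter,
                             burn_in = burn_in, adapt = adapt, seed = seed,
                             quiet = TRUE, ...))
}
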