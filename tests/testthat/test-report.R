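sim_config_small <- function(models = c(1, 2), seed = 3) {
  list(simulation = list(n_pairs = 25, n_species = 20, n_families = 5,
                         generating_model = 1),
       models = models, chains = 2, iter = 500, burn_in = 200, adapt = 200,
       seed = seed)
}

test_that("run_analysis produces a complete report for a model subset", {
  out <- tempfile("report")
  rep <- suppressMessages(run_analysis(sim_config_small(models = c(1, 2)),
                                       out_dir = out, figures = FALSE,
                                       quiet = TRUE))
  expect_s3_class(rep, "psf_report")
  expect_equal(nrow(rep$loo_table), 2)
  expect_setequal(rep$loo_table$model, c("model 1", "model 2"))
  expect_equal(min(rep$loo_table$delta_loo), 0)
  # delta column consistent with the loo column exactly
  expect_equal(rep$loo_table$delta_loo,
               rep$loo_table$loo - min(rep$loo_table$loo))
  expect_true(file.exists(file.path(out, "loo_table.csv")))
  expect_true(file.exists(file.path(out, "pairs.csv")))
  expect_true(file.exists(file.path(out, "posterior_model1.csv")))
  expect_true(file.exists(file.path(out, "run_log.txt")))
})

test_that("the report is deterministic: same config and seed, identical exports", {
  o1 <- tempfile("rep1"); o2 <- tempfile("rep2")
  r1 <- suppressMessages(run_analysis(sim_config_small(), out_dir = o1,
                                      figures = FALSE, quiet = TRUE))
  r2 <- suppressMessages(run_analysis(sim_config_small(), out_dir = o2,
                                      figures = FALSE, quiet = TRUE))
  for (f in c("loo_table.csv", "pairs.csv", "compilation.csv",
              "posterior_model1.csv", "posterior_model2.csv")) {
    expect_identical(unname(tools::md5sum(file.path(o1, f))),
                     unname(tools::md5sum(file.path(o2, f))),
                     label = f)
  }
  expect_identical(r1$loo_table$loo, r2$loo_table$loo)
})

test_that("a failing model is reported and the run continues", {
  cfg <- sim_config_small(models = c(1, 99))
  out <- tempfile("partial")
  rep <- suppressMessages(run_analysis(cfg, out_dir = out, figures = FALSE,
                                       quiet = TRUE))
  expect_s3_class(rep$fits$model1, "psf_fit")
  expect_type(rep$fits$model99, "character")
  expect_equal(nrow(rep$loo_table), 1)
  expect_true(any(grepl("FAILED", rep$log)))
})

test_that("YAML configuration files drive the same analysis", {
  cfg <- sim_config_small()
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  out <- tempfile("yamlrep")
  rep <- suppressMessages(run_analysis(path, out_dir = out, figures = FALSE,
                                       quiet = TRUE))
  expect_equal(nrow(rep$loo_table), 2)
})

test_that("the dissimilarity scatter exposes one red mean per pair", {
  pr1 <- make_pairs(list(c(0.2, -0.1, 0.4)), t_myr = 250)
  p1 <- plot_dissimilarity(pr1)
  means <- attr(p1, "pair_means")
  expect_equal(nrow(means), 1)
  expect_equal(means$r, mean(c(0.2, -0.1, 0.4)))
  sim <- simulate_pairs(simulation_config(n_pairs = 80, n_species = 50,
                                          n_families = 10, seed = 19))
  prn <- assemble_pairs(sim$table)
  pn <- plot_dissimilarity(prn)
  expect_equal(nrow(attr(pn, "pair_means")), 80)
  expect_true(grepl(sprintf("%d feedback", nrow(prn$obs)),
                    pn$labels$caption))
})

test_that("density overlays split at 300 Myr and annotate per-bin variances", {
  sim <- simulate_pairs(simulation_config(n_pairs = 60, n_species = 40,
                                          n_families = 8, generating_model = 5,
                                          params = list(s = 0.3, nu = 4, k = -0.2),
                                          seed = 29))
  pr <- assemble_pairs(sim$table)
  fitn <- fast_fit(3, pr, seed = 2, iter = 500)
  fitt <- fast_fit(5, pr, seed = 2, iter = 500)
  p <- plot_model_fit_density(pr, list(fitn, fitt))
  bs <- attr(p, "bin_stats")
  expect_equal(nrow(bs), 2)
  expect_true(all(bs$variance >= 0))
  ov <- attr(p, "overlays")
  expect_setequal(unique(ov$model), c("model 3", "model 5"))
  # heavy-tailed fit peaks higher than the normal fit in the far bin
  far <- ov[ov$bin == levels(ov$bin)[2], ]
  expect_gt(max(far$density[far$model == "model 5"]),
            max(far$density[far$model == "model 3"]))
  # a single-value bin annotates variance 0 and warns about emptiness only
  # when a bin has no data
  pr_near <- make_pairs(list(c(0.1, 0.2), 0.3), t_myr = c(100, 200))
  expect_warning(plot_model_fit_density(pr_near, fitn), "empty")
})

test_that("an injected family-pair shift is flagged; null effects are not", {
  sim <- simulate_pairs(simulation_config(
    n_pairs = 60, n_species = 40, n_families = 6, generating_model = 6,
    params = list(beta = 0, s = 0.25, nu = 8, k = 0), sigma2_w = 0.05,
    seed = 31))
  tab <- sim$table
  # inject a strong shift for one family pair
  shift_rows <- tab$family_a == "fam01" & tab$family_b == "fam02" |
    tab$family_a == "fam02" & tab$family_b == "fam01"
  if (sum(shift_rows) < 2) {
    pick <- unique(tab$family_b[tab$family_a == "fam01"])[1]
    shift_rows <- (tab$family_a == "fam01" & tab$family_b == pick) |
      (tab$family_a == pick & tab$family_b == "fam01")
  }
  target_label <- paste(sort(c("fam01", unique(c(tab$family_b[shift_rows],
                                                 tab$family_a[shift_rows]))
                              [unique(c(tab$family_b[shift_rows],
                                        tab$family_a[shift_rows])) != "fam01"][1])),
                        collapse = "--")
  tab$A_a[shift_rows] <- tab$A_a[shift_rows] * exp(1.5)
  fit <- fast_fit(7, assemble_pairs(tab), seed = 7, iter = 800)
  eff <- attr(plot_family_effects(fit), "family_effects")
  expect_true(eff$flagged[eff$family_pair == target_label])
  # and a null run flags nothing
  sim0 <- simulate_pairs(simulation_config(
    n_pairs = 40, n_species = 30, n_families = 5, generating_model = 6,
    params = list(beta = 0, s = 0.25, nu = 8, k = 0), sigma2_w = 0.05,
    seed = 37))
  fit0 <- fast_fit(7, assemble_pairs(sim0$table), seed = 7, iter = 800)
  eff0 <- attr(plot_family_effects(fit0), "family_effects")
  expect_equal(sum(eff0$flagged), 0)
})
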