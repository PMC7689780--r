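test_that("a fixture CSV reads into typed, validated rows", {
  df <- make_compilation_df(10)
  path <- write_fixture_csv(df)
  tab <- read_compilation(path)
  expect_s3_class(tab, "psf_compilation")
  expect_equal(nrow(tab), 10)
  expect_type(tab$A_a, "double")
  expect_type(tab$whole_soil, "logical")
  expect_equal(nrow(attr(tab, "problems")), 0)
})

test_that("malformed rows are reported, not silently dropped", {
  df <- make_compilation_df(10)
  df$A_a[4] <- -1
  df$B_b[7] <- "not-a-number"
  path <- write_fixture_csv(df)
  tab <- suppressMessages(read_compilation(path))
  expect_equal(nrow(tab), 8)
  probs <- attr(tab, "problems")
  expect_setequal(probs$row, c(4, 7))
  expect_true(any(grepl("positive", probs$message)))
  expect_true(any(grepl("unparseable", probs$message)))
})

test_that("a missing required column is a schema error", {
  df <- make_compilation_df(5)
  df$phylo_distance_myr <- NULL
  path <- write_fixture_csv(df)
  expect_error(read_compilation(path), "phylo_distance_myr")
})

test_that("column mapping renames non-canonical headers", {
  df <- make_compilation_df(6)
  names(df)[names(df) == "species_a"] <- "SpeciesA"
  names(df)[names(df) == "phylo_distance_myr"] <- "PD_myr"
  path <- write_fixture_csv(df)
  m <- default_mapping()
  m[["species_a"]] <- "SpeciesA"
  m[["phylo_distance_myr"]] <- "PD_myr"
  tab <- read_compilation(path, mapping = m)
  expect_equal(nrow(tab), 6)
  expect_true(all(c("species_a", "phylo_distance_myr") %in% names(tab)))
})

test_that("whole-soil filtering keeps only whole-community feedbacks", {
  df <- make_compilation_df(10, whole_soil = c(rep(TRUE, 6), rep(FALSE, 4)))
  path <- write_fixture_csv(df)
  tab <- read_compilation(path)
  kept <- suppressMessages(filter_whole_soil(tab))
  expect_equal(nrow(kept), 6)
  expect_equal(attr(kept, "n_dropped"), 4)
  # identity on an all-whole-soil table
  all_ws <- read_compilation(write_fixture_csv(make_compilation_df(8)))
  kept2 <- suppressMessages(filter_whole_soil(all_ws))
  expect_equal(nrow(kept2), 8)
})

test_that("pairs assemble by unordered species pair with pseudoreplicates attached", {
  rows <- rbind(
    transform(make_compilation_df(1, seed = 1), species_a = "spX", species_b = "spY",
              phylo_distance_myr = 200),
    transform(make_compilation_df(1, seed = 2), species_a = "spY", species_b = "spX",
              phylo_distance_myr = 200.5),
    transform(make_compilation_df(1, seed = 3), species_a = "spX", species_b = "spY",
              phylo_distance_myr = 200),
    transform(make_compilation_df(1, seed = 4), species_a = "spX", species_b = "spZ",
              phylo_distance_myr = 600))
  tab <- read_compilation(write_fixture_csv(rows))
  pr <- assemble_pairs(tab)
  expect_equal(nrow(pr$pairs), 2)
  expect_setequal(pr$pairs$n_obs, c(3, 1))
  # observation counts sum to the table's row count
  expect_equal(sum(pr$pairs$n_obs), nrow(tab))
  expect_equal(nrow(pr$obs), nrow(tab))
  # r and var_r match direct computation on oriented rows
  or <- orient_pair(tab)
  expect_setequal(round(pr$obs$r, 10), round(compute_r(or), 10))
})

test_that("assembly is invariant to input row order", {
  df <- make_compilation_df(20, seed = 5)
  tab <- read_compilation(write_fixture_csv(df))
  tab_shuf <- read_compilation(write_fixture_csv(df[sample(20), ]))
  p1 <- assemble_pairs(tab)
  p2 <- assemble_pairs(tab_shuf)
  expect_identical(p1$pairs$pair_id, p2$pairs$pair_id)
  expect_identical(p1$pairs$t_myr, p2$pairs$t_myr)
  for (id in p1$pairs$pair_id) {
    expect_setequal(round(p1$obs$r[p1$obs$pair_id == id], 12),
                    round(p2$obs$r[p2$obs$pair_id == id], 12))
  }
})

test_that("conflicting phylogenetic distances within a pair raise an error", {
  rows <- rbind(
    transform(make_compilation_df(1, seed = 1), species_a = "spX", species_b = "spY",
              phylo_distance_myr = 200),
    transform(make_compilation_df(1, seed = 2), species_a = "spX", species_b = "spY",
              phylo_distance_myr = 250))
  tab <- read_compilation(write_fixture_csv(rows))
  expect_error(assemble_pairs(tab), "inconsistent")
})

test_that("write_pairs / read_pairs round-trips r, var_r and t bit-identically", {
  sim <- simulate_pairs(simulation_config(n_pairs = 30, n_species = 25,
                                          n_families = 5, seed = 13))
  pr <- assemble_pairs(sim$table)
  path <- tempfile(fileext = ".csv")
  write_pairs(pr, path)
  back <- read_pairs(path)
  expect_identical(back$obs$r, pr$obs$r)
  expect_identical(back$obs$var_r, pr$obs$var_r)
  expect_identical(back$pairs$t_myr, pr$pairs$t_myr)
  expect_identical(back$pairs$pair_id, pr$pairs$pair_id)
  expect_identical(back$pairs$family_pair, pr$pairs$family_pair)
})

test_that("compilation CSV emission round-trips through read_compilation", {
  sim <- simulate_pairs(simulation_config(n_pairs = 15, n_species = 15,
                                          n_families = 4, seed = 3))
  path <- tempfile(fileext = ".csv")
  emit_compilation_csv(sim, path)
  back <- read_compilation(path)
  expect_equal(nrow(back), nrow(sim$table))
  expect_identical(back$A_a, sim$table$A_a)
  expect_identical(back$phylo_distance_myr, sim$table$phylo_distance_myr)
  pr1 <- assemble_pairs(sim$table)
  pr2 <- assemble_pairs(back)
  expect_identical(pr1$obs$r, pr2$obs$r)
  expect_identical(pr1$obs$var_r, pr2$obs$var_r)
})
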