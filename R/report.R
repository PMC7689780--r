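#' Run the full phylogenetic-signal analysis end to end
#'
#' The single entry point that strings the pipeline together: read (or
#' simulate) a compilation, keep whole-soil feedbacks, assemble species
#' pairs, fit the requested models, rank them by PSIS-LOO, and write the
#' comparison table, posterior summaries, figures and a run log to an
#' output directory. The report is a pure function of (input, config,
#' seed): re-running with the same configuration reproduces identical
#' tables and data exports.
#'
#' @param config A named list or path to a YAML file with entries:
#'   \describe{
#'   \item{input}{path to a compilation CSV (exclusive with `simulation`);}
#'   \item{mapping}{optional column mapping (see [default_mapping()]);}
#'   \item{simulation}{optional list of [simulation_config()] arguments
#'     for a synthetic run;}
#'   \item{models}{integer vector of model ids to fit (default 1:7);}
#'   \item{chains, iter, burn_in, adapt, thin}{MCMC settings passed to
#'     [fit_model()] (defaults 3, 10000, 1000, 500, 1);}
#'   \item{seed}{integer master seed (default 1).}
#'   }
#' @param out_dir Output directory; by default a timestamped
#'   `psf-report-<stamp>` under the working directory.
#' @param seed Overrides `config$seed` when non-NULL.
#' @param figures Write figure PDFs (default TRUE; tables are always
#'   written).
#' @param quiet Suppress progress messages.
#' @return A list of class `"psf_report"`: `pairs`, `fits` (named list,
#'   failed models carry the error message instead of a fit), `loo_table`,
#'   `summaries`, `family_effects` (model 7 only), `out_dir`, `log`.
#' @export
run_analysis <- function(config, out_dir = NULL, seed = NULL,
                         figures = TRUE, quiet = FALSE) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(models = 1:7, chains = 3, iter = 10000, burn_in = 1000,
                   adapt = 500, thin = 1, seed = 1)
  config <- utils::modifyList(defaults, config)
  if (!is.null(seed)) config$seed <- seed
  seed <- as.integer(config$seed)
  if (is.null(out_dir)) {
    out_dir <- sprintf("psf-report-%s", format(Sys.time(), "%Y%m%d-%H%M%S"))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  t_start <- proc.time()[["elapsed"]]

  # --- data ---------------------------------------------------------------
  if (!is.null(config$simulation)) {
    sim_cfg <- do.call(simulation_config,
                       utils::modifyList(list(seed = seed),
                                         as.list(config$simulation)))
    sim <- simulate_pairs(sim_cfg)
    table <- sim$table
    emit_compilation_csv(sim, file.path(out_dir, "compilation.csv"))
    say("simulated compilation: %d feedbacks under model %d (seed %d)",
        nrow(table), sim_cfg$generating_model$model_id, seed)
  } else if (!is.null(config$input)) {
    mapping <- if (is.null(config$mapping)) default_mapping() else config$mapping
    table <- read_compilation(config$input, mapping = mapping)
    say("read %d feedbacks from %s (%d rows failed validation)",
        nrow(table), config$input, length(unique(attr(table, "problems")$row)))
  } else {
    stop("config must provide either 'input' or 'simulation'", call. = FALSE)
  }

  n_before <- nrow(table)
  table <- suppressMessages(filter_whole_soil(table))
  say("whole-soil filter: retained %d of %d feedbacks", nrow(table), n_before)
  pairs <- assemble_pairs(table)
  say("assembled %d unique species pairs (%d species, %d families)",
      nrow(pairs$pairs),
      length(unique(c(pairs$pairs$species_a, pairs$pairs$species_b))),
      length(unique(c(pairs$pairs$family_a, pairs$pairs$family_b))))
  write_pairs(pairs, file.path(out_dir, "pairs.csv"))

  # --- model fits ---------------------------------------------------------
  fits <- list()
  for (mid in config$models) {
    label <- sprintf("model%d", mid)
    fits[[label]] <- tryCatch({
      fit <- suppressWarnings(fit_model(
        mid, pairs, chains = config$chains, iter = config$iter,
        burn_in = config$burn_in, adapt = config$adapt, thin = config$thin,
        seed = seed))
      say("fitted model %d in %.1f s (max R-hat %.3f)%s", mid, fit$runtime,
          max(fit$rhat, na.rm = TRUE),
          if (is.null(fit$convergence_warning)) "" else " [convergence warning]")
      fit
    }, error = function(e) {
      say("model %d FAILED: %s", mid, conditionMessage(e))
      conditionMessage(e)
    })
  }
  ok <- vapply(fits, inherits, logical(1), what = "psf_fit")
  if (!any(ok)) stop("no model could be fitted", call. = FALSE)

  # --- comparison and summaries -------------------------------------------
  loo_table <- compare_models(fits[ok])
  utils::write.csv(as.data.frame(loo_table),
                   file.path(out_dir, "loo_table.csv"), row.names = FALSE)
  summaries <- lapply(fits[ok], posterior_summary)
  for (label in names(summaries)) {
    utils::write.csv(summaries[[label]],
                     file.path(out_dir, sprintf("posterior_%s.csv", label)),
                     row.names = FALSE)
  }

  family_effects <- NULL
  fit7 <- Filter(function(f) inherits(f, "psf_fit") && f$spec$family_effects,
                 fits)
  if (length(fit7) > 0) {
    p5 <- plot_family_effects(fit7[[1]])
    family_effects <- attr(p5, "family_effects")
    utils::write.csv(family_effects,
                     file.path(out_dir, "family_effects.csv"),
                     row.names = FALSE)
    if (figures) save_figure(p5, file.path(out_dir, "family_effects.pdf"))
  }
  if (figures) {
    save_figure(plot_dissimilarity(pairs),
                file.path(out_dir, "dissimilarity.pdf"))
    best_normal <- best_of(fits[ok], "normal")
    best_t <- best_of(fits[ok], "student_t")
    overlay_fits <- Filter(Negate(is.null), list(best_normal, best_t))
    if (length(overlay_fits) > 0) {
      save_figure(plot_model_fit_density(pairs, overlay_fits),
                  file.path(out_dir, "model_fit_density.pdf"))
    }
  }

  say("total runtime %.1f s", proc.time()[["elapsed"]] - t_start)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  structure(list(pairs = pairs, fits = fits, loo_table = loo_table,
                 summaries = summaries, family_effects = family_effects,
                 out_dir = out_dir, log = log_lines),
            class = "psf_report")
}

best_of <- function(fits, family) {
  cand <- Filter(function(f) f$spec$family == family && !f$spec$family_effects,
                 fits)
  if (length(cand) == 0) return(NULL)
  loos <- vapply(cand, function(f) psis_loo(f)$looic, numeric(1))
  cand[[which.min(loos)]]
}

save_figure <- function(p, path, width = 7, height = 5) {
  grDevices::pdf(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  print(p)
  invisible(path)
}

#' @export
print.psf_report <- function(x, ...) {
  cat("psf_report in", x$out_dir, "\n")
  print(x$pairs)
  print(x$loo_table)
  invisible(x)
}
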