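#' Scatter of dissimilarity responses against phylogenetic distance
#'
#' Replicate-level r values (x jittered for visibility) with the mean
#' response of each unique species pair overlaid in red — the standard
#' first look at whether the spread of feedback responses grows with
#' divergence time.
#'
#' @param pairs A `"psf_pairs"` object.
#' @param jitter_sd SD (Myr) of the horizontal jitter on replicate points.
#' @param seed Seed for the jitter.
#' @return A ggplot object; the underlying replicate and pair-mean tables
#'   are in its `$data` and the `"pair_means"` attribute.
#' @export
plot_dissimilarity <- function(pairs, jitter_sd = 5, seed = 1) {
  stopifnot(inherits(pairs, "psf_pairs"))
  obs <- pairs$obs
  obs$t_jit <- obs$t_myr + withr_seed(seed, stats::rnorm(nrow(obs), 0, jitter_sd))
  means <- stats::aggregate(r ~ pair_id + t_myr, data = pairs$obs, FUN = mean)
  p <- ggplot2::ggplot(obs, ggplot2::aes(x = .data$t_jit, y = .data$r)) +
    ggplot2::geom_point(colour = "steelblue", alpha = 0.4, size = 1) +
    ggplot2::geom_point(data = means,
                        ggplot2::aes(x = .data$t_myr, y = .data$r),
                        colour = "red", size = 1.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(
      x = "Phylogenetic distance (Myr)",
      y = "Dissimilarity response r",
      caption = sprintf("%d feedback responses from %d unique species pairs",
                        nrow(obs), nrow(pairs$pairs))) +
    ggplot2::theme_minimal()
  attr(p, "pair_means") <- means
  p
}

#' Density histograms of r with fitted model overlays
#'
#' Splits responses into distance classes (by default within-family,
#' <= 300 Myr, versus between-family, > 300 Myr), draws a density
#' histogram of r per class, and overlays the pair-level predictive
#' density of each supplied fitted model evaluated at the class's median
#' distance using posterior-mean parameters. The empirical variance of
#' each class is annotated. A heavy-tailed fit showing a higher peak than
#' a matched normal fit at large distances is the visual signature of
#' kurtosis in the divergence process.
#'
#' @param pairs A `"psf_pairs"` object.
#' @param fits One `"psf_fit"` or a list of them (typically the best
#'   normal and the best Student-t model).
#' @param split_myr Distance breakpoints (Myr); default 300.
#' @return A ggplot object; the overlay curves are in the
#'   `"overlays"` attribute, per-bin variances in `"bin_stats"`.
#' @export
plot_model_fit_density <- function(pairs, fits, split_myr = 300) {
  stopifnot(inherits(pairs, "psf_pairs"))
  if (inherits(fits, "psf_fit")) fits <- list(fits)
  obs <- pairs$obs
  breaks <- c(-Inf, split_myr, Inf)
  lab <- c(sprintf("within %s Myr", paste(split_myr, collapse = "/")),
           sprintf("beyond %s Myr", paste(split_myr, collapse = "/")))
  if (length(split_myr) > 1) {
    lab <- paste("bin", seq_len(length(split_myr) + 1))
    breaks <- c(-Inf, split_myr, Inf)
  }
  obs$bin <- cut(obs$t_myr, breaks, labels = lab)
  bins <- levels(obs$bin)[table(obs$bin) > 0]
  empty <- setdiff(levels(obs$bin), bins)
  if (length(empty) > 0) {
    warning("empty distance bin(s) omitted: ", paste(empty, collapse = ", "),
            call. = FALSE)
  }
  obs <- obs[obs$bin %in% bins, , drop = FALSE]
  obs$bin <- droplevels(obs$bin)

  bin_stats <- do.call(rbind, lapply(levels(obs$bin), function(b) {
    v <- obs$r[obs$bin == b]
    data.frame(bin = b, n = length(v),
               variance = if (length(v) > 1) stats::var(v) else 0,
               median_t = stats::median(obs$t_myr[obs$bin == b]),
               stringsAsFactors = FALSE)
  }))

  grid <- seq(min(obs$r) - 0.5, max(obs$r) + 0.5, length.out = 301)
  overlays <- do.call(rbind, lapply(fits, function(fit) {
    ps <- posterior_summary(fit)
    par <- stats::setNames(ps$mean, ps$parameter)
    do.call(rbind, lapply(seq_len(nrow(bin_stats)), function(i) {
      t100 <- bin_stats$median_t[i] / 100
      data.frame(bin = bin_stats$bin[i],
                 model = sprintf("model %d", fit$spec$model_id),
                 r = grid,
                 density = pair_level_density(fit$spec, par, grid, t100),
                 mean = pair_level_mean(fit$spec, par, t100),
                 stringsAsFactors = FALSE)
    }))
  }))
  overlays$bin <- factor(overlays$bin, levels = levels(obs$bin))

  p <- ggplot2::ggplot(obs, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_line(data = overlays,
                       ggplot2::aes(y = .data$density, colour = .data$model)) +
    ggplot2::geom_text(data = bin_stats,
                       ggplot2::aes(x = Inf, y = Inf,
                                    label = sprintf("var = %.3f", .data$variance)),
                       hjust = 1.1, vjust = 1.5, size = 3, inherit.aes = FALSE) +
    ggplot2::facet_wrap(~bin, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Dissimilarity response r", y = "Density") +
    ggplot2::theme_minimal()
  attr(p, "overlays") <- overlays
  attr(p, "bin_stats") <- bin_stats
  p
}

# marginal pair-level density of r*_j at distance t100, at fixed parameters
pair_level_density <- function(spec, par, grid, t100) {
  mu <- if (spec$trend) par[["beta"]] * t100 else 0
  if (spec$family == "normal") {
    v <- par[["sigma"]]^2 +
      (if (spec$variance_growth) par[["k"]] * t100 else 0)
    stats::dnorm(grid, mu, sqrt(v))
  } else {
    df <- par[["nu"]] + par[["k"]] * t100
    stats::dt((grid - mu) / par[["s"]], df) / par[["s"]]
  }
}

pair_level_mean <- function(spec, par, t100) {
  if (spec$trend) par[["beta"]] * t100 else 0
}

#' Family-pair deviations from the overall mean response (model 7)
#'
#' Posterior means and 95% credible intervals of the family-pair effects
#' alpha_f, plotted against the mean phylogenetic distance of the species
#' pairs in each family pair. Family pairs whose 95% interval excludes
#' zero are flagged (plotted red and labelled); within-family estimates
#' sit left of the dashed partition line.
#'
#' @param fit A `"psf_fit"` of model 7.
#' @param partition_myr Position (Myr) of the within/between-family
#'   partition line. Default 300.
#' @return A ggplot object; the per-family-pair table (estimate, interval,
#'   `flagged`, `within_family`, mean distance, n) is in the
#'   `"family_effects"` attribute.
#' @export
plot_family_effects <- function(fit, partition_myr = 300) {
  stopifnot(inherits(fit, "psf_fit"))
  if (!fit$spec$family_effects) {
    stop("family-effect plot requires a model with family-pair terms (model 7)",
         call. = FALSE)
  }
  pd <- fit$pair_data
  m <- as.matrix(fit$draws)
  acols <- grep("^alpha\\[", colnames(m), value = TRUE)
  aidx <- as.integer(sub("^alpha\\[(\\d+)\\]$", "\\1", acols))
  eff <- do.call(rbind, lapply(order(aidx), function(o) {
    v <- m[, acols[o]]
    q <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
    data.frame(family_pair = pd$fam_levels[aidx[o]],
               estimate = mean(v), q2.5 = q[1], q97.5 = q[2],
               stringsAsFactors = FALSE)
  }))
  per_pair <- data.frame(fam = pd$fam_levels[pd$fam], t = pd$t100 * 100,
                         stringsAsFactors = FALSE)
  agg <- stats::aggregate(t ~ fam, data = per_pair, FUN = mean)
  cnt <- stats::aggregate(t ~ fam, data = per_pair, FUN = length)
  eff$mean_t_myr <- agg$t[match(eff$family_pair, agg$fam)]
  eff$n_pairs <- cnt$t[match(eff$family_pair, cnt$fam)]
  eff$flagged <- eff$q2.5 > 0 | eff$q97.5 < 0
  fams <- strsplit(eff$family_pair, "--", fixed = TRUE)
  eff$within_family <- vapply(fams, function(f) length(unique(f)) == 1, logical(1))

  p <- ggplot2::ggplot(eff, ggplot2::aes(x = .data$mean_t_myr,
                                         y = .data$estimate)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$q2.5, ymax = .data$q97.5),
                           width = 0, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$flagged), size = 1.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::geom_text(data = eff[eff$flagged, , drop = FALSE],
                       ggplot2::aes(label = .data$family_pair),
                       vjust = -1, size = 2.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = partition_myr, linetype = 2) +
    ggplot2::labs(x = "Mean phylogenetic distance of family pair (Myr)",
                  y = "Deviation of mean response from overall mean") +
    ggplot2::theme_minimal()
  attr(p, "family_effects") <- eff
  p
}
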