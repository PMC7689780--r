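#' Construct and validate pairwise feedback experiments
#'
#' A pairwise plant-soil feedback experiment grows two plant species, A and
#' B, in soil cultivated by each of them, yielding four biomass means:
#' `A_a` (species A in A-cultivated soil), `A_b` (A in B-soil), `B_a`
#' (B in A-soil) and `B_b` (B in B-soil), each with a standard error.
#' `feedback_experiment()` builds a validated one-or-more-row data frame of
#' such experiments; all downstream operations are vectorised over rows.
#'
#' @param species_a,species_b Taxon labels (character).
#' @param A_a,A_b,B_a,B_b Biomass means; strictly positive and finite.
#' @param se_A_a,se_A_b,se_B_a,se_B_b Standard errors of the four means;
#'   non-negative and finite. Default 0 (means taken at face value).
#' @param treatment Free-text treatment label.
#' @param soil_fraction Proportion of whole-soil inoculum in (0, 1].
#' @param whole_soil Logical; `TRUE` when the experiment used a whole soil
#'   community rather than a microbial fraction.
#'
#' @return A data frame of class `"feedback_experiment"`.
#' @export
#' @examples
#' exp <- feedback_experiment("A", "B", A_a = 1, A_b = 0.8, B_a = 1, B_b = 0.9)
#' compute_r(exp)
feedback_experiment <- function(species_a, species_b,
                                A_a, A_b, B_a, B_b,
                                se_A_a = 0, se_A_b = 0, se_B_a = 0, se_B_b = 0,
                                treatment = "", soil_fraction = 1,
                                whole_soil = TRUE) {
  x <- data.frame(
    species_a = as.character(species_a), species_b = as.character(species_b),
    A_a = as.numeric(A_a), A_b = as.numeric(A_b),
    B_a = as.numeric(B_a), B_b = as.numeric(B_b),
    se_A_a = as.numeric(se_A_a), se_A_b = as.numeric(se_A_b),
    se_B_a = as.numeric(se_B_a), se_B_b = as.numeric(se_B_b),
    treatment = as.character(treatment),
    soil_fraction = as.numeric(soil_fraction),
    whole_soil = as.logical(whole_soil),
    stringsAsFactors = FALSE
  )
  validate_feedback_experiment(x)
  class(x) <- c("feedback_experiment", class(x))
  x
}

# Shared input validation: every biomass strictly positive and finite, every
# SE non-negative and finite. Errors name the offending field.
validate_feedback_experiment <- function(x) {
  biomass_fields <- c("A_a", "A_b", "B_a", "B_b")
  se_fields <- c("se_A_a", "se_A_b", "se_B_a", "se_B_b")
  missing <- setdiff(c(biomass_fields, se_fields), names(x))
  if (length(missing) > 0) {
    stop("feedback experiment is missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (f in biomass_fields) {
    v <- x[[f]]
    bad <- !is.finite(v) | v <= 0
    if (any(bad)) {
      stop(sprintf(
        "invalid biomass in field '%s': must be strictly positive and finite (row %d has %s)",
        f, which(bad)[1], format(v[which(bad)[1]])), call. = FALSE)
    }
  }
  for (f in se_fields) {
    v <- x[[f]]
    bad <- !is.finite(v) | v < 0
    if (any(bad)) {
      stop(sprintf(
        "invalid standard error in field '%s': must be non-negative and finite (row %d has %s)",
        f, which(bad)[1], format(v[which(bad)[1]])), call. = FALSE)
    }
  }
  invisible(x)
}

#' Dissimilarity response r of a pairwise feedback experiment
#'
#' Computes the dissimilarity in feedback response of two plant species as
#' the difference of natural-log biomass ratios across the two cultivated
#' soils:
#' \deqn{r = \ln(A_a / B_a) - \ln(A_b / B_b)}
#' with the numerator of the left-hand log ratio fixed as performance in
#' conspecific soil, so a positive r means the species perform better
#' overall in conspecific than heterospecific soil (a positive feedback).
#' r = 0 means the two species responded identically (in proportional
#' terms) to the two soil communities. r is invariant to relabelling the
#' two species and to rescaling either species' biomasses by a constant.
#'
#' @param exp A [feedback_experiment()] (or any data frame carrying the
#'   four biomass columns `A_a`, `A_b`, `B_a`, `B_b`).
#' @return Numeric vector of dissimilarity responses, one per row. Unitless.
#' @seealso [compute_r_variance()], [orient_pair()]
#' @export
compute_r <- function(exp) {
  validate_feedback_experiment(exp)
  log(exp$A_a / exp$B_a) - log(exp$A_b / exp$B_b)
}

#' Sampling variance of the dissimilarity response
#'
#' First-order delta-method variance of r on the log scale, the standard
#' sampling variance of a log response ratio:
#' \deqn{\sigma^2_r = (se_{A_a}/A_a)^2 + (se_{B_a}/B_a)^2 +
#'       (se_{A_b}/A_b)^2 + (se_{B_b}/B_b)^2}
#' The approximation is accurate when each SE is small relative to its mean
#' (within 5% of the true Monte-Carlo variance for SE/mean <= 0.1).
#' Zero standard errors contribute zero variance: such observations are
#' taken at face value.
#'
#' @inheritParams compute_r
#' @return Numeric vector of sampling variances (unitless).
#' @export
compute_r_variance <- function(exp) {
  validate_feedback_experiment(exp)
  if (any(exp$se_A_a == 0 & exp$se_A_b == 0 & exp$se_B_a == 0 & exp$se_B_b == 0)) {
    message("note: some experiments have all-zero standard errors; ",
            "their r values are treated as measured without error")
  }
  (exp$se_A_a / exp$A_a)^2 + (exp$se_B_a / exp$B_a)^2 +
    (exp$se_A_b / exp$A_b)^2 + (exp$se_B_b / exp$B_b)^2
}

#' Canonical orientation of a pairwise feedback experiment
#'
#' Arranges the two species of each experiment in a canonical order (the
#' lexicographically smaller taxon label plays the role of species A) while
#' preserving the conspecific-numerator convention of [compute_r()]. Because
#' swapping the species swaps both the numerator species and the soil roles,
#' r is algebraically invariant under relabelling:
#' \eqn{\ln(B_b/A_b) - \ln(B_a/A_a) = \ln(A_a/B_a) - \ln(A_b/B_b)},
#' so orientation changes neither the sign nor the magnitude of r. It exists
#' to give every unordered species pair a stable identity.
#'
#' @inheritParams compute_r
#' @return The experiment(s) with species roles canonically arranged.
#' @export
orient_pair <- function(exp) {
  validate_feedback_experiment(exp)
  swap <- exp$species_b < exp$species_a
  if (!any(swap)) return(exp)
  out <- exp
  # full role swap: labels, conspecific<->conspecific, heterospecific<->heterospecific
  out$species_a[swap] <- exp$species_b[swap]
  out$species_b[swap] <- exp$species_a[swap]
  out$A_a[swap] <- exp$B_b[swap]
  out$B_b[swap] <- exp$A_a[swap]
  out$A_b[swap] <- exp$B_a[swap]
  out$B_a[swap] <- exp$A_b[swap]
  out$se_A_a[swap] <- exp$se_B_b[swap]
  out$se_B_b[swap] <- exp$se_A_a[swap]
  out$se_A_b[swap] <- exp$se_B_a[swap]
  out$se_B_a[swap] <- exp$se_A_b[swap]
  for (f in c("family_a", "family_b", "origin_a", "origin_b",
              "functional_group_a", "functional_group_b")) {
    fa <- f
    fb <- sub("_a$", "_b", f)
    if (endsWith(f, "_a") && fa %in% names(exp) && fb %in% names(exp)) {
      out[[fa]][swap] <- exp[[fb]][swap]
      out[[fb]][swap] <- exp[[fa]][swap]
    }
  }
  out
}
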