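#' Default column mapping for feedback compilation tables
#'
#' The compilation dialect used by this package is a plain CSV with one row
#' per replicate pairwise feedback. `default_mapping()` returns the map from
#' the package's canonical field names to the column headers expected in the
#' file; pass a modified copy (or a YAML file read with
#' [yaml::read_yaml()]) to [read_compilation()] when your file uses
#' different headers.
#'
#' Required fields: the two taxon labels, the four biomass means and their
#' standard errors, the phylogenetic distance (Myr) and the whole-soil flag.
#' The remaining fields (families, study metadata, covariates) are carried
#' through but not modelled.
#'
#' @return Named character vector: canonical field -> file column.
#' @export
default_mapping <- function() {
  fields <- c("study_id", "species_a", "species_b", "family_a", "family_b",
              "A_a", "A_b", "B_a", "B_b",
              "se_A_a", "se_A_b", "se_B_a", "se_B_b",
              "phylo_distance_myr", "whole_soil", "soil_fraction",
              "treatment", "glasshouse", "ecosystem",
              "origin_a", "origin_b",
              "functional_group_a", "functional_group_b")
  stats::setNames(fields, fields)
}

required_fields <- function() {
  c("species_a", "species_b", "A_a", "A_b", "B_a", "B_b",
    "se_A_a", "se_A_b", "se_B_a", "se_B_b",
    "phylo_distance_myr", "whole_soil")
}

#' Read a feedback compilation table
#'
#' Reads a CSV/TSV compilation of pairwise plant-soil feedback experiments,
#' renames columns to the canonical dialect via `mapping`, coerces types and
#' validates each row (positive finite biomasses, non-negative finite
#' standard errors, non-missing finite distance and whole-soil flag).
#' Malformed rows are not silently dropped: they are removed from the
#' returned table and collected, with reasons, in the `"problems"`
#' attribute.
#'
#' Lines starting with `#` are treated as comments (the synthetic-data
#' writer records its seed that way).
#'
#' @param path Path to the delimited file.
#' @param mapping Named character vector canonical-field -> file-column; see
#'   [default_mapping()]. May also be a path to a YAML file holding such a
#'   map.
#' @param delim Field delimiter, default `","`.
#' @return A data frame of class `"psf_compilation"` with canonical
#'   columns, a `"problems"` attribute (data frame of row/field/message),
#'   and class `"feedback_experiment"` behaviour for the core computations.
#' @export
read_compilation <- function(path, mapping = default_mapping(), delim = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.character(mapping) && length(mapping) == 1 && file.exists(mapping)) {
    mapping <- unlist(yaml::read_yaml(mapping))
  }
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE, quote = "\"",
                           fileEncoding = "UTF-8")
  miss <- setdiff(required_fields(), names(mapping))
  if (length(miss) > 0) {
    stop("column mapping lacks required field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(unname(mapping[required_fields()]), names(raw))
  if (length(absent) > 0) {
    stop("input file lacks required column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }

  present <- mapping[unname(mapping) %in% names(raw)]
  tab <- as.data.frame(matrix(nrow = nrow(raw), ncol = 0))
  for (canon in names(present)) tab[[canon]] <- raw[[present[[canon]]]]

  num_fields <- c("A_a", "A_b", "B_a", "B_b",
                  "se_A_a", "se_A_b", "se_B_a", "se_B_b",
                  "phylo_distance_myr", "soil_fraction")
  problems <- data.frame(row = integer(), field = character(),
                         message = character(), stringsAsFactors = FALSE)
  bad <- rep(FALSE, nrow(tab))
  note <- function(rows, field, msg) {
    if (length(rows) == 0) return()
    problems <<- rbind(problems, data.frame(row = rows, field = field,
                                            message = msg,
                                            stringsAsFactors = FALSE))
    bad[rows] <<- TRUE
  }
  for (f in intersect(num_fields, names(tab))) {
    v <- suppressWarnings(as.numeric(tab[[f]]))
    note(which(!is.na(tab[[f]]) & is.na(v)), f, "unparseable numeric")
    tab[[f]] <- v
  }
  tab$whole_soil <- parse_logical(tab$whole_soil)
  for (f in c("A_a", "A_b", "B_a", "B_b")) {
    note(which(!bad & (!is.finite(tab[[f]]) | tab[[f]] <= 0)), f,
         "biomass must be strictly positive and finite")
  }
  for (f in c("se_A_a", "se_A_b", "se_B_a", "se_B_b")) {
    note(which(!bad & (!is.finite(tab[[f]]) | tab[[f]] < 0)), f,
         "standard error must be non-negative and finite")
  }
  note(which(!bad & (!is.finite(tab$phylo_distance_myr) |
                       tab$phylo_distance_myr < 0)),
       "phylo_distance_myr", "distance must be non-negative and finite")
  note(which(!bad & is.na(tab$whole_soil)), "whole_soil",
       "whole-soil flag must be TRUE/FALSE")

  out <- tab[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "problems") <- problems
  class(out) <- c("psf_compilation", "feedback_experiment", "data.frame")
  if (nrow(problems) > 0) {
    message(sprintf("read_compilation: %d row(s) failed validation (see attr(., 'problems'))",
                    length(unique(problems$row))))
  }
  out
}

parse_logical <- function(v) {
  if (is.logical(v)) return(v)
  s <- toupper(trimws(as.character(v)))
  out <- rep(NA, length(s))
  out[s %in% c("TRUE", "T", "1", "YES", "Y", "WHOLE")] <- TRUE
  out[s %in% c("FALSE", "F", "0", "NO", "N", "FRACTION")] <- FALSE
  out
}

#' Restrict a compilation to whole-soil-community experiments
#'
#' Feedbacks measured with only a fraction of the soil community (for
#' example mycorrhizal fungi alone) are expected to differ from whole-soil
#' feedbacks and would obscure the phylogenetic signal of interest, so the
#' analysis retains whole-soil rows only.
#'
#' @param table A `"psf_compilation"` from [read_compilation()].
#' @return The filtered compilation; the number of rows dropped is reported
#'   via `message()` and stored in the `"n_dropped"` attribute.
#' @export
filter_whole_soil <- function(table) {
  if (!"whole_soil" %in% names(table)) {
    stop("compilation has no 'whole_soil' column", call. = FALSE)
  }
  keep <- !is.na(table$whole_soil) & table$whole_soil
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  dropped <- nrow(table) - nrow(out)
  message(sprintf("filter_whole_soil: retained %d of %d feedbacks (%d dropped)",
                  nrow(out), nrow(table), dropped))
  attr(out, "n_dropped") <- dropped
  attr(out, "problems") <- attr(table, "problems")
  class(out) <- class(table)
  out
}

#' Assemble replicate feedbacks into species pairs
#'
#' Groups the rows of a (filtered) compilation by unordered species pair,
#' computes each replicate's dissimilarity response r and sampling variance
#' via [compute_r()] and [compute_r_variance()] under the canonical
#' orientation, and attaches the pair-level phylogenetic distance and
#' family-pair label. Replicate feedbacks of the same pair (for example the
#' same pair measured under different resource treatments) are treated as
#' pseudoreplicates of that pair, to be absorbed by the within-pair variance
#' of the hierarchical models rather than counted as independent pairs.
#'
#' @param table A `"psf_compilation"`.
#' @param distance_tol Maximum allowed spread (Myr) of the phylogenetic
#'   distance reported for the same species pair across rows; a larger
#'   spread raises a consistency error. Default 1 Myr.
#' @return An object of class `"psf_pairs"`: a list with
#'   \describe{
#'   \item{pairs}{one row per unique pair: `pair_id`, species, families,
#'     `family_pair`, `t_myr`, `n_obs`;}
#'   \item{obs}{one row per replicate: `pair_id`, `replicate`, `r`,
#'     `var_r`, `t_myr`.}
#'   }
#' @export
assemble_pairs <- function(table, distance_tol = 1) {
  validate_feedback_experiment(table)
  if (nrow(table) == 0) stop("no feedbacks to assemble", call. = FALSE)
  if (!"family_a" %in% names(table)) table$family_a <- NA_character_
  if (!"family_b" %in% names(table)) table$family_b <- NA_character_
  tab <- orient_pair(table)
  tab$r <- compute_r(tab)
  tab$var_r <- suppressMessages(compute_r_variance(tab))
  key <- paste(tab$species_a, tab$species_b, sep = "||")
  ord <- order(key)
  tab <- tab[ord, , drop = FALSE]
  key <- key[ord]

  idx <- split(seq_len(nrow(tab)), key)
  pair_ids <- names(idx)
  pairs <- do.call(rbind, lapply(pair_ids, function(k) {
    rows <- tab[idx[[k]], , drop = FALSE]
    tspread <- diff(range(rows$phylo_distance_myr))
    if (tspread > distance_tol) {
      stop(sprintf(
        "inconsistent phylogenetic distances for pair %s / %s: spread %.3g Myr exceeds %.3g",
        rows$species_a[1], rows$species_b[1], tspread, distance_tol),
        call. = FALSE)
    }
    fams <- sort(c(rows$family_a[1], rows$family_b[1]), na.last = TRUE)
    data.frame(
      pair_id = k,
      species_a = rows$species_a[1], species_b = rows$species_b[1],
      family_a = rows$family_a[1], family_b = rows$family_b[1],
      family_pair = paste(fams, collapse = "--"),
      t_myr = mean(rows$phylo_distance_myr),
      n_obs = nrow(rows),
      stringsAsFactors = FALSE
    )
  }))
  obs <- do.call(rbind, lapply(pair_ids, function(k) {
    rows <- tab[idx[[k]], , drop = FALSE]
    data.frame(
      pair_id = k,
      replicate = seq_len(nrow(rows)),
      r = rows$r,
      var_r = rows$var_r,
      t_myr = mean(rows$phylo_distance_myr),
      stringsAsFactors = FALSE
    )
  }))
  rownames(pairs) <- rownames(obs) <- NULL
  out <- list(pairs = pairs, obs = obs)
  class(out) <- "psf_pairs"
  out
}

#' @export
print.psf_pairs <- function(x, ...) {
  nsp <- length(unique(c(x$pairs$species_a, x$pairs$species_b)))
  fams <- unique(c(x$pairs$family_a, x$pairs$family_b))
  fams <- fams[!is.na(fams)]
  cat(sprintf(
    "psf_pairs: %d feedbacks, %d unique species pairs, %d species, %d families\n",
    nrow(x$obs), nrow(x$pairs), nsp, length(fams)))
  cat(sprintf("phylogenetic distance: %.0f-%.0f Myr; replicates per pair: %d-%d\n",
              min(x$pairs$t_myr), max(x$pairs$t_myr),
              min(x$pairs$n_obs), max(x$pairs$n_obs)))
  invisible(x)
}

#' Write / read assembled pairs as CSV
#'
#' One row per replicate observation with the pair-level fields repeated;
#' numeric values are written with 17 significant digits so that
#' `read_pairs(write_pairs(x))` reproduces `r`, `var_r` and `t_myr`
#' bit-identically.
#'
#' @param pairs A `"psf_pairs"` object.
#' @param path Output CSV path.
#' @return `write_pairs` invisibly returns `path`; `read_pairs` returns a
#'   `"psf_pairs"` object.
#' @export
write_pairs <- function(pairs, path) {
  stopifnot(inherits(pairs, "psf_pairs"))
  m <- merge(pairs$obs,
             pairs$pairs[, c("pair_id", "species_a", "species_b",
                             "family_a", "family_b", "family_pair")],
             by = "pair_id", sort = TRUE)
  m <- m[order(m$pair_id, m$replicate), , drop = FALSE]
  for (f in c("r", "var_r", "t_myr")) m[[f]] <- format_full(m[[f]])
  utils::write.csv(m, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (f in c("r", "var_r", "t_myr")) m[[f]] <- as.numeric(m[[f]])
  obs <- m[, c("pair_id", "replicate", "r", "var_r", "t_myr")]
  first <- !duplicated(m$pair_id)
  pairs <- m[first, c("pair_id", "species_a", "species_b",
                      "family_a", "family_b", "family_pair", "t_myr")]
  pairs$n_obs <- as.integer(table(m$pair_id)[pairs$pair_id])
  rownames(pairs) <- rownames(obs) <- NULL
  out <- list(pairs = pairs, obs = obs)
  class(out) <- "psf_pairs"
  out
}

format_full <- function(x) {
  formatC(x, format = "g", digits = 17)
}

#' Write a compilation table in the package CSV dialect
#'
#' @param table A `"psf_compilation"` (or compatible data frame).
#' @param path Output CSV path.
#' @param seed Optional integer recorded in a `#`-comment header line.
#' @return Invisibly, `path`.
#' @export
write_compilation <- function(table, path, seed = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  tab <- as.data.frame(table)
  num <- vapply(tab, is.numeric, logical(1))
  for (f in names(tab)[num]) tab[[f]] <- format_full(tab[[f]])
  utils::write.csv(tab, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}
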