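#' Cohort pipeline configuration
#'
#' Bundles the inclusion filters, income coarse-graining and balanced
#' resampling parameters used by the cohort pipeline. Defaults follow the
#' study design this package implements: working-age adults (25-65
#' inclusive), native-born, in full-time employment, self-identified as
#' White only or Black only; income coarse-grained at $27,500 / $52,500 /
#' $77,500 into four ordered classes; 1000 balanced resamples with the
#' per-cell draw size set to the smallest joint predictor cell.
#'
#' @param age_min,age_max inclusive age bounds in years.
#' @param allowed_races category labels retained by the race filter.
#' @param nativity_required,employment_required logical; apply the
#'   corresponding filter.
#' @param native_labels,fulltime_labels category labels that count as
#'   native-born / full-time employed.
#' @param income_cutpoints strictly increasing USD thresholds; incomes
#'   below the first cutpoint fall in the lowest class, incomes at or
#'   above the last in the highest.
#' @param income_labels labels of the ordered income classes (one more
#'   than there are cutpoints).
#' @param n_resamples number of balanced subsample replicates.
#' @param cell_size per-cell draw size; `NULL` (default) uses the
#'   smallest joint predictor cell count.
#' @param replace draw within cells with replacement? Default `FALSE`.
#' @param seed master seed; per-replicate substreams are spawned from it
#'   so increasing `n_resamples` does not reshuffle earlier replicates.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(age_min = 25, age_max = 65,
                          allowed_races = c("White", "Black"),
                          nativity_required = TRUE,
                          employment_required = TRUE,
                          native_labels = "Native",
                          fulltime_labels = "Full-time",
                          income_cutpoints = c(27500, 52500, 77500),
                          income_labels = c("Low", "Lower-Middle",
                                            "Upper-Middle", "High"),
                          n_resamples = 1000,
                          cell_size = NULL,
                          replace = FALSE,
                          seed = 1L) {
  if (any(diff(income_cutpoints) <= 0))
    stop("income_cutpoints must be strictly increasing")
  if (length(income_labels) != length(income_cutpoints) + 1)
    stop("need one income label per class")
  if (n_resamples < 1) stop("n_resamples must be >= 1")
  structure(list(
    age_min = age_min, age_max = age_max,
    allowed_races = allowed_races,
    nativity_required = nativity_required,
    employment_required = employment_required,
    native_labels = native_labels,
    fulltime_labels = fulltime_labels,
    income_cutpoints = income_cutpoints,
    income_labels = income_labels,
    n_resamples = as.integer(n_resamples),
    cell_size = cell_size,
    replace = replace,
    seed = as.integer(seed)), class = "cohort_config")
}

person_cols <- c("race", "sex", "age", "nativity", "employment",
                 "income", "health")

#' Construct a validated person-level table
#'
#' @param df data.frame with columns `race`, `sex`, `age`, `nativity`,
#'   `employment`, `income` (USD), `health` (ordinal 1-5).
#' @param year calendar year the records refer to.
#' @param provenance free-text description of the source.
#' @return `df` with class `person_table` and `year` / `provenance`
#'   attributes.
#' @export
person_table <- function(df, year = NA_integer_, provenance = "unknown") {
  missing_cols <- setdiff(person_cols, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!nrow(df)) stop("person table is empty")
  if (any(!df$health %in% 1:5)) stop("health must be in 1..5")
  if (any(df$income < 0)) stop("income must be >= 0")
  if (any(df$age < 0)) stop("age must be >= 0")
  structure(df, year = year, provenance = provenance,
            class = c("person_table", class(df)))
}

#' Load a person-level table from delimited text
#'
#' Reads a delimited file and maps its columns onto the canonical person
#' record fields. Rows whose required fields cannot be parsed (missing
#' values, health outside 1-5, negative income or age) are dropped and
#' counted; the counts are attached as the `"dropped"` attribute and
#' reported via a message.
#'
#' @param path file path.
#' @param column_map named character vector mapping canonical field names
#'   (`race`, `sex`, `age`, `nativity`, `employment`, `income`, `health`)
#'   to column names in the file; defaults to the identity mapping. A
#'   documented starting mapping for CPS ASEC person-file variable names
#'   ships at `system.file("extdata", "asec_column_map.json", package =
#'   "pidsect")`.
#' @param delim field delimiter (default comma).
#' @param year,provenance metadata stored on the result.
#' @return a [person_table()].
#' @export
load_person_table <- function(path, column_map = NULL, delim = ",",
                              year = NA_integer_, provenance = path) {
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(column_map))
    column_map <- stats::setNames(person_cols, person_cols)
  missing_map <- setdiff(person_cols, names(column_map))
  if (length(missing_map))
    stop("column_map must cover: ", paste(missing_map, collapse = ", "))
  missing_cols <- setdiff(unname(column_map[person_cols]), names(raw))
  if (length(missing_cols))
    stop("mapped column(s) absent from file: ",
         paste(missing_cols, collapse = ", "))
  df <- data.frame(
    race = as.character(raw[[column_map[["race"]]]]),
    sex = as.character(raw[[column_map[["sex"]]]]),
    age = suppressWarnings(as.integer(raw[[column_map[["age"]]]])),
    nativity = as.character(raw[[column_map[["nativity"]]]]),
    employment = as.character(raw[[column_map[["employment"]]]]),
    income = suppressWarnings(as.numeric(raw[[column_map[["income"]]]])),
    health = suppressWarnings(as.integer(raw[[column_map[["health"]]]])),
    stringsAsFactors = FALSE)
  bad <- is.na(df$age) | df$age < 0 |
    is.na(df$income) | df$income < 0 |
    is.na(df$health) | !df$health %in% 1:5 |
    is.na(df$race) | is.na(df$sex) | is.na(df$nativity) |
    is.na(df$employment)
  dropped <- sum(bad)
  if (dropped)
    message(dropped, " row(s) dropped (unparseable or out-of-support fields)")
  df <- df[!bad, , drop = FALSE]
  if (!nrow(df)) stop("no parseable rows in ", path)
  out <- person_table(df, year = year, provenance = provenance)
  attr(out, "dropped") <- dropped
  out
}

#' Apply the cohort inclusion filters
#'
#' Keeps records with age within the configured inclusive bounds, race
#' among the allowed categories, and (when required) native-born and
#' full-time employed. The result does not depend on filter order; if the
#' table empties, the error names the first filter (in age, race,
#' nativity, employment order) that emptied it. Attrition counts per
#' filter are attached as the `"attrition"` attribute.
#'
#' @param table a [person_table()].
#' @param config a [cohort_config()].
#' @return the filtered [person_table()].
#' @export
apply_filters <- function(table, config = cohort_config()) {
  keep_age <- table$age >= config$age_min & table$age <= config$age_max
  keep_race <- table$race %in% config$allowed_races
  keep_nat <- if (config$nativity_required)
    table$nativity %in% config$native_labels else rep(TRUE, nrow(table))
  keep_emp <- if (config$employment_required)
    table$employment %in% config$fulltime_labels else rep(TRUE, nrow(table))
  keeps <- list(age = keep_age, race = keep_race,
                nativity = keep_nat, employment = keep_emp)
  cum <- rep(TRUE, nrow(table))
  attrition <- integer(0)
  for (nm in names(keeps)) {
    before <- sum(cum)
    cum <- cum & keeps[[nm]]
    attrition[nm] <- before - sum(cum)
    if (!sum(cum))
      stop("cohort empty after the '", nm, "' filter")
  }
  out <- table[cum, , drop = FALSE]
  out <- person_table(out, year = attr(table, "year"),
                      provenance = attr(table, "provenance"))
  attr(out, "attrition") <- attrition
  out
}

#' Coarse-grain income into ordered classes
#'
#' Maps non-negative USD incomes into ordered classes at the configured
#' cutpoints: with the defaults, \[0, 27499\] is Low, \[27500, 52499\]
#' Lower-Middle, \[52500, 77499\] Upper-Middle and 77500 or more High.
#'
#' @param income numeric vector of non-negative incomes (USD).
#' @param cutpoints strictly increasing thresholds; an income equal to a
#'   cutpoint falls in the class above it.
#' @param labels class labels (one more than cutpoints).
#' @return an ordered factor with one level per class.
#' @export
coarse_grain_income <- function(income,
                                cutpoints = c(27500, 52500, 77500),
                                labels = c("Low", "Lower-Middle",
                                           "Upper-Middle", "High")) {
  if (any(!is.finite(income)) || any(income < 0))
    stop("income must be finite and >= 0")
  if (any(diff(cutpoints) <= 0))
    stop("cutpoints must be strictly increasing")
  code <- findInterval(income, cutpoints)
  factor(labels[code + 1], levels = labels, ordered = TRUE)
}

# deterministic per-replicate seed substreams: the first k draws of
# sample.int are a stable prefix, so growing n_resamples keeps earlier
# replicate streams unchanged
replicate_seeds <- function(master, n) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, n)
}

as_outcome_factor <- function(x) {
  # declared factor levels are kept (including unobserved ones)
  if (is.factor(x)) x else factor(x, levels = sort(unique(x)))
}

#' Balanced-resample mixture distribution (effective information)
#'
#' Builds the maximum-entropy intervention distribution for a set of
#' predictor variables: for each of `n_resamples` replicates an equal
#' number of records is drawn from every joint predictor cell, the
#' empirical joint distribution of (predictors, outcome) is formed, and
#' the equal-weight mixture of all replicate distributions is returned.
#' Because every cell contributes exactly the same number of draws, the
#' joint predictor marginal of the mixture is uniform by construction, so
#' mutual informations computed from it are effective information: the
#' information that would flow if identities were assigned uniformly at
#' random.
#'
#' @param table a [person_table()] (or any data.frame with the columns).
#' @param predictors character vector of predictor column names.
#' @param outcome outcome column name.
#' @param config a [cohort_config()]; `n_resamples`, `cell_size`,
#'   `replace` and `seed` are used.
#' @return an object of class `effective_dist`: `dist` (a
#'   [joint_dist()] over predictors and outcome),
#'   `predictor_marginal_flatness` (max deviation of the joint predictor
#'   marginal from uniform), `cell_size`, `n_resamples`, `cell_counts`
#'   and `seed`.
#' @export
balanced_resample_mixture <- function(table, predictors, outcome,
                                      config = cohort_config()) {
  stopifnot(all(c(predictors, outcome) %in% names(table)))
  pred_fac <- lapply(table[predictors], as_outcome_factor)
  cell <- interaction(pred_fac, drop = FALSE, sep = "\r")
  counts <- table(cell)
  if (any(counts == 0))
    stop("empty joint predictor cell(s): ",
         paste(gsub("\r", ":", names(counts)[counts == 0]), collapse = ", "))
  m <- config$cell_size %||% min(counts)
  if (!config$replace && m > min(counts))
    stop("cell_size exceeds the smallest cell (", min(counts),
         ") for draws without replacement")
  out_fac <- as_outcome_factor(table[[outcome]])
  n_out <- nlevels(out_fac)
  out_code <- as.integer(out_fac)
  cell_idx <- split(seq_len(nrow(table)), cell)
  n_cells <- length(cell_idx)
  seeds <- replicate_seeds(config$seed, config$n_resamples)
  acc <- matrix(0L, nrow = n_cells, ncol = n_out)
  for (r in seq_len(config$n_resamples)) {
    set.seed(seeds[r])
    for (ci in seq_len(n_cells)) {
      idx <- cell_idx[[ci]]
      draw <- idx[sample.int(length(idx), m, replace = config$replace)]
      acc[ci, ] <- acc[ci, ] + tabulate(out_code[draw], nbins = n_out)
    }
  }
  dims <- unname(c(vapply(pred_fac, nlevels, integer(1)), n_out))
  dn <- c(lapply(pred_fac, levels), list(levels(out_fac)))
  names(dn) <- c(predictors, outcome)
  # acc rows follow interaction() order = first predictor fastest
  arr <- array(acc / sum(acc), dim = dims, dimnames = dn)
  dist <- joint_dist(arr)
  pm <- as.vector(marginal(dist, predictors))
  structure(list(
    dist = dist,
    predictor_marginal_flatness = max(abs(pm - 1 / n_cells)),
    cell_size = m,
    n_resamples = config$n_resamples,
    cell_counts = stats::setNames(as.integer(counts),
                                  gsub("\r", ":", names(counts))),
    predictors = predictors,
    outcome = outcome,
    seed = config$seed), class = "effective_dist")
}

#' @export
print.effective_dist <- function(x, ...) {
  cat("Effective (balanced-resample mixture) distribution\n")
  cat("  predictors:", paste(x$predictors, collapse = ", "),
      " outcome:", x$outcome, "\n")
  cat("  replicates:", x$n_resamples, " per-cell draws:", x$cell_size, "\n")
  cat("  predictor marginal flatness:",
      format(x$predictor_marginal_flatness, digits = 3), "\n")
  invisible(x)
}

#' Partial information decomposition of an effective distribution
#'
#' Delegates to [pid_imin()] or [pid_broja()] on the mixture
#' distribution of an [balanced_resample_mixture()] result (a plain
#' [joint_dist()] is also accepted).
#'
#' @param effdist an `effective_dist` or [joint_dist()].
#' @param sources list of character vectors of variable names.
#' @param target character vector.
#' @param method `"imin"` or `"broja"` (the latter for two sources only).
#' @return a `pid_result`.
#' @export
effective_pid <- function(effdist, sources, target,
                          method = c("imin", "broja")) {
  method <- match.arg(method)
  dist <- if (inherits(effdist, "effective_dist")) effdist$dist else effdist
  if (method == "imin") pid_imin(dist, sources, target)
  else pid_broja(dist, sources, target)
}

default_triads <- function() {
  list(
    race_sex_income = list(sources = list("race", "sex"), target = "income"),
    race_income_health = list(sources = list("race", "income"),
                              target = "health"),
    race_sex_income_health = list(sources = list("race", "sex", "income"),
                                  target = "health"))
}

# filtered analysis table: coarse income, factor health
analysis_table <- function(table, config) {
  tab <- apply_filters(table, config)
  df <- data.frame(
    race = factor(tab$race, levels = config$allowed_races),
    sex = as_outcome_factor(tab$sex),
    income = coarse_grain_income(tab$income, config$income_cutpoints,
                                 config$income_labels),
    health = factor(tab$health, levels = 1:5, ordered = TRUE),
    income_usd = tab$income,
    stringsAsFactors = FALSE)
  df
}

#' Per-year and decade PID analysis
#'
#' Runs the full pipeline (inclusion filters, income coarse-graining,
#' balanced resampling, PID) on one or more years of person-level
#' records, for one or more (sources, target) triads. The defaults are
#' the three study triads: (race, sex) about income, (race, income)
#' about health, and (race, sex, income) about health. For each
#' year/triad the whole-minus-sum heuristic on the mixture distribution
#' is recorded alongside the decomposition, and atom fractions are
#' summarised as mean and sd across years.
#'
#' @param tables a named list of [person_table()]s (names are the years),
#'   or a single table.
#' @param triads named list of `list(sources = , target = )`
#'   specifications over the analysis columns `race`, `sex`, `income`
#'   (coarse-grained), `health`; default [default_triads()].
#' @param config a [cohort_config()].
#' @param method `"imin"` (required for the three-source triad) or
#'   `"broja"`.
#' @return an object of class `decade_pid`: `atoms` (long data.frame:
#'   year, triad, atom, category, bits, fraction), `wms` (year, triad,
#'   whole-minus-sum bits), `summary` (triad, atom, mean/sd fraction),
#'   and `results` (nested list of `pid_result`s).
#' @export
decade_analysis <- function(tables, triads = default_triads(),
                            config = cohort_config(),
                            method = c("imin", "broja")) {
  method <- match.arg(method)
  if (inherits(tables, "person_table")) tables <- list(tables)
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    names(tables) <- vapply(seq_along(tables), function(i) {
      y <- attr(tables[[i]], "year")
      if (is.na(y %||% NA)) as.character(i) else as.character(y)
    }, character(1))
  if (is.null(names(triads)))
    names(triads) <- vapply(triads, function(tr)
      paste(c(unlist(tr$sources), tr$target), collapse = "_"), character(1))
  atoms <- list()
  wms <- list()
  results <- list()
  for (yr in names(tables)) {
    df <- analysis_table(tables[[yr]], config)
    yr_cfg <- config
    yr_cfg$seed <- config$seed + match(yr, names(tables)) - 1L
    results[[yr]] <- list()
    for (tn in names(triads)) {
      tr <- triads[[tn]]
      preds <- unlist(tr$sources)
      eff <- balanced_resample_mixture(df, preds, tr$target, yr_cfg)
      res <- effective_pid(eff, tr$sources, tr$target, method = method)
      cl <- classify_atoms(res)
      atoms[[length(atoms) + 1]] <- data.frame(
        year = yr, triad = tn, atom = names(res$atoms),
        category = unname(cl$categories),
        bits = unname(res$atoms), fraction = unname(res$fractions),
        stringsAsFactors = FALSE)
      wms[[length(wms) + 1]] <- data.frame(
        year = yr, triad = tn,
        wms_bits = whole_minus_sum(eff$dist, tr$sources, tr$target),
        joint_mi = res$joint_mi, stringsAsFactors = FALSE)
      results[[yr]][[tn]] <- res
    }
  }
  atoms <- do.call(rbind, atoms)
  wms <- do.call(rbind, wms)
  agg <- stats::aggregate(fraction ~ triad + atom, data = atoms,
                          FUN = function(v) c(mean = mean(v),
                                              sd = stats::sd(v)))
  summary_df <- data.frame(
    triad = agg$triad, atom = agg$atom,
    mean_fraction = agg$fraction[, "mean"],
    sd_fraction = ifelse(is.na(agg$fraction[, "sd"]), 0,
                         agg$fraction[, "sd"]))
  structure(list(atoms = atoms, wms = wms, summary = summary_df,
                 results = results, method = method, triads = triads),
            class = "decade_pid")
}

#' @export
print.decade_pid <- function(x, digits = 4, ...) {
  cat("Decade PID analysis (", x$method, "), ",
      length(unique(x$atoms$year)), " year(s), ",
      length(x$triads), " triad(s)\n", sep = "")
  s <- x$summary
  s$mean_fraction <- round(s$mean_fraction, digits)
  s$sd_fraction <- round(s$sd_fraction, digits)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Write decade-analysis outputs to a directory
#'
#' Writes the tidy long atom table (`atoms.csv`), the whole-minus-sum
#' series (`wms.csv`), one flat PID result file per year and triad, and
#' a JSON run manifest recording the configuration and triads.
#'
#' @param res a `decade_pid`.
#' @param dir output directory (created if needed).
#' @param config the [cohort_config()] used, stored in the manifest.
#' @return `dir`, invisibly.
#' @export
write_decade_results <- function(res, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$atoms, file.path(dir, "atoms.csv"), row.names = FALSE)
  utils::write.csv(res$wms, file.path(dir, "wms.csv"), row.names = FALSE)
  for (yr in names(res$results))
    for (tn in names(res$results[[yr]]))
      write_pid_result(res$results[[yr]][[tn]],
                       file.path(dir, paste0("pid_", yr, "_", tn, ".txt")))
  manifest <- list(
    method = res$method,
    years = names(res$results),
    triads = lapply(res$triads, function(tr)
      list(sources = lapply(tr$sources, as.character),
           target = as.character(tr$target))),
    config = if (!is.null(config)) unclass(config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}
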