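#' Robustness sweeps: subsampling and noise injection
#'
#' Stress tests of the effective-information PID pipeline: how the
#' whole-minus-sum heuristic and the redundancy / synergy fractions
#' respond when the input table is subsampled to smaller sizes, or when
#' a growing fraction of rows has its associations destroyed by
#' independent column-wise shuffling.
#'
#' @name robustness
NULL

run_triad_once <- function(df, triad, config) {
  preds <- unlist(triad$sources)
  eff <- balanced_resample_mixture(df, preds, triad$target, config)
  res <- pid_imin(eff$dist, triad$sources, triad$target)
  cl <- classify_atoms(res)
  c(wms = whole_minus_sum(eff$dist, triad$sources, triad$target),
    red_frac = unname(cl$fractions[["redundant"]]),
    syn_frac = unname(cl$fractions[["synergistic"]]),
    joint_mi = res$joint_mi)
}

sweep_result <- function(records, axis_name) {
  long <- do.call(rbind, records)
  summ <- stats::aggregate(
    cbind(wms, red_frac, syn_frac) ~ axis, data = long,
    FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  structure(list(values = long, summary = summ, axis = axis_name),
            class = "pid_sweep")
}

#' @export
print.pid_sweep <- function(x, digits = 4, ...) {
  cat("PID robustness sweep over", x$axis, "\n")
  s <- x$summary
  for (col in c("wms", "red_frac", "syn_frac"))
    s[[col]] <- round(s[[col]], digits)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Subsample-size sweep
#'
#' For each subset size, repeatedly draws that many records at random,
#' reruns the full balanced-resample + PID pipeline on the subset, and
#' records the whole-minus-sum statistic and the redundant / synergistic
#' fractions of the joint mutual information. Small subsets
#' systematically over-estimate whole-minus-sum (plug-in entropy bias);
#' the estimates converge toward the full-sample value as the subset
#' grows.
#'
#' @param table a [person_table()]; filters and income coarse-graining
#'   are applied first.
#' @param triad `list(sources = , target = )` over the analysis columns
#'   (`race`, `sex`, `income`, `health`).
#' @param sizes integer vector of subset sizes; default 20
#'   logarithmically spaced sizes from 250 to the full (filtered) table.
#' @param reps replicates per size (default 600).
#' @param config a [cohort_config()]; its `n_resamples` applies to every
#'   pipeline rerun, so sweeps are typically run with a reduced value.
#' @param seed master seed for the sweep (subset draws and pipeline
#'   resampling).
#' @return a `pid_sweep`: long per-replicate values and per-size
#'   mean/sd summaries.
#' @export
subsample_sweep <- function(table, triad, sizes = NULL, reps = 600,
                            config = cohort_config(n_resamples = 50),
                            seed = 1L) {
  df <- analysis_table(table, config)
  n <- nrow(df)
  if (is.null(sizes))
    sizes <- unique(round(exp(seq(log(250), log(n), length.out = 20))))
  if (any(sizes > n)) stop("subset sizes must not exceed the table size")
  preds <- unlist(triad$sources)
  n_cells <- prod(vapply(df[preds], function(v) nlevels(as_outcome_factor(v)),
                         integer(1)))
  seeds <- matrix(replicate_seeds(seed, length(sizes) * reps),
                  nrow = length(sizes))
  records <- list()
  for (i in seq_along(sizes)) {
    sz <- sizes[i]
    if (sz < n_cells) {
      warning("size ", sz, " smaller than the number of predictor cells; skipped")
      next
    }
    for (r in seq_len(reps)) {
      set.seed(seeds[i, r])
      # the full table is used as-is so the sweep end point reproduces
      # the un-subsetted pipeline exactly
      sub <- if (sz == n) df else df[sample.int(n, sz), , drop = FALSE]
      counts <- table(interaction(lapply(sub[preds], as_outcome_factor)))
      if (any(counts == 0)) next # this draw missed a cell entirely
      cfg <- config
      cfg$seed <- seeds[i, r]
      stat <- run_triad_once(sub, triad, cfg)
      records[[length(records) + 1]] <- data.frame(
        axis = sz, rep = r, t(stat))
    }
  }
  sweep_result(records, "subset size")
}

# independent column-wise shuffle of the selected rows: destroys the
# association between columns within the selection while preserving
# every marginal distribution
shuffle_rows <- function(df, rows) {
  for (col in names(df))
    df[[col]][rows] <- df[[col]][rows][sample.int(length(rows))]
  df
}

#' Noise-injection sweep
#'
#' For each noise fraction `f`, selects `ceiling(f * n)` rows and
#' shuffles each column independently among the selected rows —
#' destroying the associations those rows carry while preserving all
#' marginal distributions — then reruns the pipeline and records the
#' same statistics as [subsample_sweep()].
#'
#' @inheritParams subsample_sweep
#' @param fractions numeric vector of noise fractions in `[0, 1]`;
#'   default 20 logarithmically spaced values from 0.0001 (0.01%) to 0.1
#'   (10%).
#' @return a `pid_sweep`.
#' @export
noise_sweep <- function(table, triad, fractions = NULL, reps = 600,
                        config = cohort_config(n_resamples = 50),
                        seed = 1L) {
  df <- analysis_table(table, config)
  n <- nrow(df)
  if (is.null(fractions))
    fractions <- exp(seq(log(1e-4), log(0.1), length.out = 20))
  if (any(fractions > 1)) stop("noise fractions must not exceed 1")
  if (any(fractions < 0)) stop("noise fractions must be >= 0")
  seeds <- matrix(replicate_seeds(seed, length(fractions) * reps),
                  nrow = length(fractions))
  records <- list()
  for (i in seq_along(fractions)) {
    f <- fractions[i]
    k <- ceiling(f * n)
    for (r in seq_len(reps)) {
      set.seed(seeds[i, r])
      noisy <- if (k > 0) shuffle_rows(df, sample.int(n, k)) else df
      cfg <- config
      cfg$seed <- seeds[i, r]
      stat <- run_triad_once(noisy, triad, cfg)
      records[[length(records) + 1]] <- data.frame(
        axis = f, rep = r, t(stat))
    }
  }
  sweep_result(records, "noise fraction")
}
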