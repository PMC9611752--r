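#' Identity predicates and their conjunction / disjunction
#'
#' An identity predicate matches records (or joint outcomes) whose value
#' of one categorical variable equals a given category, e.g.
#' `identity_pred("race", "Black")`. Two predicates can be combined with
#' [pred_and()] (conjunction: both identities) or [pred_or()] (inclusive
#' disjunction: at least one identity).
#'
#' @param variable variable / column name.
#' @param category matching category label.
#' @return an `identity_pred` (or `identity_cond` for the combinations).
#' @export
identity_pred <- function(variable, category) {
  structure(list(variable = as.character(variable),
                 category = as.character(category)),
            class = "identity_pred")
}

#' @rdname identity_pred
#' @param a,b two `identity_pred`s.
#' @export
pred_and <- function(a, b) {
  stopifnot(inherits(a, "identity_pred"), inherits(b, "identity_pred"))
  structure(list(op = "and", a = a, b = b), class = "identity_cond")
}

#' @rdname identity_pred
#' @export
pred_or <- function(a, b) {
  stopifnot(inherits(a, "identity_pred"), inherits(b, "identity_pred"))
  structure(list(op = "or", a = a, b = b), class = "identity_cond")
}

cond_mask <- function(cond, get_var) {
  if (is.null(cond)) return(NULL)
  if (inherits(cond, "identity_pred"))
    return(get_var(cond$variable) == cond$category)
  ma <- get_var(cond$a$variable) == cond$a$category
  mb <- get_var(cond$b$variable) == cond$b$category
  if (cond$op == "and") ma & mb else ma | mb
}

#' Conditional expected outcome
#'
#' Probability-weighted mean of an outcome over the records (or joint
#' outcomes) satisfying a condition built from identity predicates; with
#' no condition, the grand mean. On a [person_table()] this is the
#' unweighted mean over matching records; on an `effective_dist` (or
#' [joint_dist()]) it is the mixture-probability-weighted mean over the
#' outcome support, using `outcome_values` (or the numeric
#' interpretation of the support labels) as the outcome scale. The two
#' routes agree on balanced tables.
#'
#' @param data a [person_table()], `effective_dist` or [joint_dist()].
#' @param outcome outcome column / variable name.
#' @param condition `NULL`, an [identity_pred()], or [pred_and()] /
#'   [pred_or()] of two predicates.
#' @param outcome_values optional named numeric vector mapping outcome
#'   support labels to numeric values (distribution route only).
#' @return expected outcome in outcome units.
#' @export
expected_outcome <- function(data, outcome, condition = NULL,
                             outcome_values = NULL) {
  if (inherits(data, "effective_dist")) data <- data$dist
  if (inherits(data, "joint_dist")) {
    vars <- data$variables
    if (!outcome %in% vars) stop("unknown outcome variable '", outcome, "'")
    grid <- expand.grid(data$supports, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    p <- as.vector(data$prob)
    mask <- cond_mask(condition, function(v) {
      if (!v %in% vars) stop("unknown condition variable '", v, "'")
      grid[[v]]
    })
    if (!is.null(mask)) { p <- p[mask]; grid <- grid[mask, , drop = FALSE] }
    if (sum(p) <= 0) stop("condition has zero probability mass")
    vals <- if (!is.null(outcome_values)) {
      v <- outcome_values[grid[[outcome]]]
      if (anyNA(v)) stop("outcome_values must cover the outcome support")
      v
    } else {
      v <- suppressWarnings(as.numeric(grid[[outcome]]))
      if (anyNA(v)) stop("outcome support is not numeric; supply outcome_values")
      v
    }
    return(sum(p * vals) / sum(p))
  }
  if (!outcome %in% names(data)) stop("unknown outcome column '", outcome, "'")
  mask <- cond_mask(condition, function(v) {
    if (!v %in% names(data)) stop("unknown condition column '", v, "'")
    data[[v]]
  })
  y <- data[[outcome]]
  if (!is.null(mask)) y <- y[mask]
  if (!length(y)) stop("condition matches no records")
  mean(y)
}

#' Decompose an intersectional outcome gap into shared and synergistic shifts
#'
#' Computes the expected outcome overall (baseline), conditional on the
#' inclusive disjunction of two identity predicates (at least one of the
#' identities), and conditional on their conjunction (both identities).
#' The redundant shift `disjunctive - baseline` is the expected outcome
#' change associated with holding at least one of the identities without
#' knowing which; the synergistic shift `conjunctive - disjunctive` is
#' the additional change specific to holding both, above and beyond the
#' shared component. The two shifts sum to `conjunctive - baseline`
#' exactly, and the result is symmetric in the two predicates.
#'
#' When `config` is supplied and `data` is a [person_table()], all three
#' expectations are taken over the balanced resamples of the joint
#' (pred_a, pred_b) predictor cells (equal-weight mixture across
#' replicates), matching the effective-information analysis; otherwise
#' they are plain record means (or mixture expectations for a
#' distribution input).
#'
#' @param data a [person_table()], `effective_dist` or [joint_dist()].
#' @param outcome outcome column / variable name (e.g. raw `income`).
#' @param pred_a,pred_b two [identity_pred()]s on distinct variables.
#' @param config optional [cohort_config()] activating the
#'   balanced-resample route (person-table input only).
#' @param outcome_values passed to [expected_outcome()] for
#'   distribution inputs.
#' @return an `outcome_decomposition`: `baseline`, `disjunctive`,
#'   `conjunctive`, `redundant_shift`, `synergistic_shift`.
#' @export
intersection_decomposition <- function(data, outcome, pred_a, pred_b,
                                       config = NULL,
                                       outcome_values = NULL) {
  stopifnot(inherits(pred_a, "identity_pred"),
            inherits(pred_b, "identity_pred"))
  if (identical(pred_a$variable, pred_b$variable))
    stop("the two predicates must be on distinct variables")
  if (!is.null(config) && !inherits(data, "joint_dist") &&
      !inherits(data, "effective_dist")) {
    ex <- balanced_expectations(data, outcome, pred_a, pred_b, config)
  } else {
    ex <- c(
      baseline = expected_outcome(data, outcome, NULL, outcome_values),
      disjunctive = expected_outcome(data, outcome, pred_or(pred_a, pred_b),
                                     outcome_values),
      conjunctive = expected_outcome(data, outcome, pred_and(pred_a, pred_b),
                                     outcome_values))
  }
  structure(list(
    baseline = unname(ex[["baseline"]]),
    disjunctive = unname(ex[["disjunctive"]]),
    conjunctive = unname(ex[["conjunctive"]]),
    redundant_shift = unname(ex[["disjunctive"]] - ex[["baseline"]]),
    synergistic_shift = unname(ex[["conjunctive"]] - ex[["disjunctive"]]),
    pred_a = pred_a, pred_b = pred_b, outcome = outcome),
    class = "outcome_decomposition")
}

# expectations over balanced resamples of the joint (var_a, var_b) cells:
# every replicate draws m records per cell, so cells carry equal weight
# and pooled means equal the mixture expectations
balanced_expectations <- function(table, outcome, pred_a, pred_b, config) {
  va <- pred_a$variable; vb <- pred_b$variable
  stopifnot(all(c(va, vb, outcome) %in% names(table)))
  fa <- as_outcome_factor(table[[va]])
  fb <- as_outcome_factor(table[[vb]])
  cell <- interaction(fa, fb, drop = FALSE, sep = "\r")
  counts <- table(cell)
  if (any(counts == 0))
    stop("empty joint predictor cell(s): ",
         paste(gsub("\r", ":", names(counts)[counts == 0]), collapse = ", "))
  m <- config$cell_size %||% min(counts)
  if (!config$replace && m > min(counts))
    stop("cell_size exceeds the smallest cell for draws without replacement")
  y <- as.numeric(table[[outcome]])
  cell_idx <- split(seq_len(nrow(table)), cell)
  in_a <- vapply(strsplit(names(cell_idx), "\r", fixed = TRUE),
                 function(s) s[1] == pred_a$category, logical(1))
  in_b <- vapply(strsplit(names(cell_idx), "\r", fixed = TRUE),
                 function(s) s[2] == pred_b$category, logical(1))
  if (!any(in_a & in_b))
    stop("conjunction condition has zero mass (category absent)")
  seeds <- replicate_seeds(config$seed, config$n_resamples)
  sums <- numeric(length(cell_idx))
  for (r in seq_len(config$n_resamples)) {
    set.seed(seeds[r])
    for (ci in seq_along(cell_idx)) {
      idx <- cell_idx[[ci]]
      draw <- idx[sample.int(length(idx), m, replace = config$replace)]
      sums[ci] <- sums[ci] + sum(y[draw])
    }
  }
  cell_means <- sums / (m * config$n_resamples)
  c(baseline = mean(cell_means),
    disjunctive = mean(cell_means[in_a | in_b]),
    conjunctive = mean(cell_means[in_a & in_b]))
}

#' @export
print.outcome_decomposition <- function(x, digits = 2, ...) {
  lab <- function(p) paste0(p$variable, "=", p$category)
  cat("Expected-outcome decomposition of '", x$outcome, "'\n", sep = "")
  cat("  A = ", lab(x$pred_a), ", B = ", lab(x$pred_b), "\n", sep = "")
  cat(sprintf("  E[Y]         = %.*f\n", digits, x$baseline))
  cat(sprintf("  E[Y | A or B]  = %.*f\n", digits, x$disjunctive))
  cat(sprintf("  E[Y | A and B] = %.*f\n", digits, x$conjunctive))
  cat(sprintf("  redundant shift  (disj - base): %.*f\n", digits,
              x$redundant_shift))
  cat(sprintf("  synergistic shift (conj - disj): %.*f\n", digits,
              x$synergistic_shift))
  invisible(x)
}
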