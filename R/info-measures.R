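#' Shannon entropy of a (macro-)variable in bits
#'
#' Entropy of the marginal distribution of a group of variables treated as
#' a single macro-variable, `H = -sum(p * log2(p))` with the convention
#' that empty cells (`p == 0`) contribute nothing. All information
#' measures in this package are in bits (base-2 logarithms).
#'
#' @param dist a [joint_dist()].
#' @param group character vector of variable names.
#' @return entropy in bits (non-negative scalar).
#' @export
entropy <- function(dist, group) {
  p <- as.vector(marginal(dist, group))
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Conditional entropy H(target | given) in bits
#'
#' Computed as `H(target, given) - H(given)`; always between 0 and
#' `H(target)` (up to floating point).
#'
#' @inheritParams entropy
#' @param target,given disjoint character vectors of variable names.
#' @return conditional entropy in bits.
#' @export
conditional_entropy <- function(dist, target, given) {
  target <- check_vars(dist, target, "target")
  given <- check_vars(dist, given, "given")
  if (length(intersect(target, given)))
    stop("target and given groups must be disjoint")
  entropy(dist, c(target, given)) - entropy(dist, given)
}

#' Mutual information I(a; b) in bits
#'
#' `I(a; b) = H(a) - H(a | b)`: the reduction in uncertainty about one
#' (macro-)variable from observing the other. Symmetric and non-negative
#' up to floating point. Groups of several variables are treated as a
#' single macro-variable, so `mutual_information(d, c("x1", "x2"), "y")`
#' is the joint mutual information of both sources about the target.
#'
#' @inheritParams entropy
#' @param a,b disjoint character vectors of variable names.
#' @return mutual information in bits.
#' @export
mutual_information <- function(dist, a, b) {
  a <- check_vars(dist, a, "a")
  b <- check_vars(dist, b, "b")
  if (length(intersect(a, b)))
    stop("groups must be disjoint")
  entropy(dist, a) - conditional_entropy(dist, a, b)
}

#' Whole-minus-sum synergy heuristic
#'
#' The difference between the joint mutual information of all sources
#' about the target and the sum of the marginal mutual informations:
#' positive values indicate synergy-dominated dependence (the whole
#' carries more than the sum of its parts), negative values
#' redundancy-dominated dependence. For two sources this equals
#' `Syn - Red` of the partial information decomposition.
#'
#' @inheritParams entropy
#' @param sources list of (pairwise disjoint) character vectors.
#' @param target character vector, disjoint from every source.
#' @return signed bits.
#' @export
whole_minus_sum <- function(dist, sources, target) {
  if (!is.list(sources)) sources <- as.list(sources)
  if (length(sources) < 2)
    stop("whole_minus_sum needs at least 2 sources")
  sources <- lapply(sources, check_vars, dist = dist, what = "source")
  all_src <- unlist(sources)
  if (anyDuplicated(all_src))
    stop("sources must be pairwise disjoint")
  target <- check_vars(dist, target, "target")
  if (length(intersect(all_src, target)))
    stop("target must be disjoint from the sources")
  joint <- mutual_information(dist, all_src, target)
  joint - sum(vapply(sources, function(s)
    mutual_information(dist, s, target), numeric(1)))
}
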