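#' Finite categorical joint probability distributions
#'
#' A `joint_dist` is the substrate for every information measure in this
#' package: a named probability table over an ordered set of categorical
#' variables, each with an ordered support of category labels. Internally
#' the pmf is stored as a dense numeric array with one dimension per
#' variable and `dimnames` carrying the supports, so marginalisation is a
#' plain `apply()` over dimensions.
#'
#' @param prob numeric array (or vector for a single variable) of
#'   probabilities. `dimnames(prob)` must be a fully named list: names are
#'   the variable names, entries are the per-variable supports.
#' @param renormalize if `TRUE`, divide by the total mass (which must be
#'   positive). Renormalisation is always explicit, never silent: a table
#'   whose mass differs from 1 by more than the tolerance is rejected
#'   unless this flag is set.
#' @param tol tolerance on the total-mass check (default `1e-9`).
#'
#' @return An object of class `joint_dist` with elements `variables`
#'   (character), `supports` (named list of character) and `prob` (array).
#' @examples
#' p <- array(0.25, dim = c(2, 2),
#'            dimnames = list(x = c("0", "1"), y = c("0", "1")))
#' d <- joint_dist(p)
#' entropy(d, "x")
#' @export
joint_dist <- function(prob, renormalize = FALSE, tol = 1e-9) {
  if (is.null(dim(prob))) {
    if (is.null(names(prob))) stop("single-variable pmf needs named states")
    nm <- names(prob)
    prob <- array(as.numeric(prob), dim = length(prob))
    dimnames(prob) <- list(x = nm)
  }
  dn <- dimnames(prob)
  if (is.null(dn) || is.null(names(dn)) || any(names(dn) == ""))
    stop("prob must have fully named dimnames (variable -> support)")
  if (anyDuplicated(names(dn)))
    stop("duplicated variable names")
  for (v in names(dn)) {
    if (anyDuplicated(dn[[v]]))
      stop("duplicated category labels in support of '", v, "'")
  }
  if (any(!is.finite(prob)) || any(prob < -tol))
    stop("probabilities must be finite and non-negative")
  prob[prob < 0] <- 0
  total <- sum(prob)
  if (renormalize) {
    if (total <= 0) stop("cannot renormalize a zero-mass table")
    prob <- prob / total
  } else if (abs(total - 1) > tol) {
    stop(sprintf(
      "probabilities sum to %.12f, not 1 (tol %g); use renormalize = TRUE",
      total, tol))
  }
  structure(
    list(variables = names(dn), supports = dn, prob = prob),
    class = "joint_dist")
}

#' Build a joint distribution from a table of counts
#'
#' @param counts a `table`/array of non-negative counts with named
#'   dimnames, or a data.frame of categorical columns plus an optional
#'   count column.
#' @param count_col for the data.frame form, name of the count column; if
#'   `NULL` every row counts once.
#' @param supports optional named list fixing the support (and its order)
#'   of each variable; levels absent from the data get probability 0.
#'   Defaults to the observed (or factor) levels.
#' @return a `joint_dist` (maximum-likelihood plug-in estimate; no
#'   pseudocounts are added).
#' @export
joint_dist_from_counts <- function(counts, count_col = NULL, supports = NULL) {
  if (is.data.frame(counts)) {
    df <- counts
    if (!is.null(count_col)) {
      w <- df[[count_col]]
      if (is.null(w)) stop("count column '", count_col, "' not found")
      df <- df[setdiff(names(df), count_col)]
    } else {
      w <- rep(1, nrow(df))
    }
    if (!ncol(df)) stop("no categorical columns")
    fs <- lapply(names(df), function(v) {
      lev <- if (!is.null(supports) && !is.null(supports[[v]])) supports[[v]]
             else if (is.factor(df[[v]])) levels(df[[v]])
             else sort(unique(as.character(df[[v]])))
      factor(as.character(df[[v]]), levels = lev)
    })
    names(fs) <- names(df)
    if (any(vapply(fs, anyNA, logical(1))))
      stop("values outside the declared supports")
    counts <- tapply(w, fs, sum, default = 0)
    if (is.null(dim(counts))) { # single variable
      counts <- array(counts, dim = length(counts),
                      dimnames = stats::setNames(list(names(counts)), names(df)))
    }
  }
  if (sum(counts) <= 0) stop("total count must be positive")
  joint_dist(counts / sum(counts), tol = 1e-6)
}

#' @export
print.joint_dist <- function(x, ...) {
  cat("Joint distribution over", length(x$variables), "variable(s):\n")
  for (v in x$variables)
    cat("  ", v, ": {", paste(x$supports[[v]], collapse = ", "), "}\n", sep = "")
  cat("  mass:", format(sum(x$prob), digits = 12), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_vars <- function(dist, vars, what = "variable group") {
  vars <- unique(as.character(vars))
  if (!length(vars)) stop(what, " must be non-empty")
  bad <- setdiff(vars, dist$variables)
  if (length(bad))
    stop("unknown variable name(s): ", paste(bad, collapse = ", "))
  vars
}

#' Marginal probability table of a group of variables
#'
#' @param dist a [joint_dist()].
#' @param vars character vector of variable names treated as a single
#'   macro-variable.
#' @return a numeric array over the requested variables (in distribution
#'   order), summing to the same mass as `dist`.
#' @export
marginal <- function(dist, vars) {
  vars <- check_vars(dist, vars)
  keep <- match(vars, dist$variables)
  keep <- sort(keep)
  m <- apply(dist$prob, keep, sum)
  if (is.null(dim(m))) {
    m <- array(m, dim = length(m),
               dimnames = dist$supports[keep])
  }
  m
}

#' Write / read a joint distribution as delimited text
#'
#' The on-disk format is two columns: the joint outcome (one category per
#' variable, semicolon-joined in variable order) and its probability.
#' Commented header lines record the variable names and supports so the
#' round trip is lossless, including zero-probability cells and support
#' order.
#'
#' @param dist a [joint_dist()].
#' @param path file path.
#' @param sep column delimiter (default tab).
#' @return `write_joint_dist` returns `path` invisibly; `read_joint_dist`
#'   returns a [joint_dist()].
#' @export
write_joint_dist <- function(dist, path, sep = "\t") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# variables: ", paste(dist$variables, collapse = ";")), con)
  for (v in dist$variables)
    writeLines(paste0("# support ", v, ": ",
                      paste(dist$supports[[v]], collapse = ";")), con)
  grid <- expand.grid(dist$supports, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  key <- do.call(paste, c(grid, sep = ";"))
  p <- as.vector(dist$prob)
  writeLines(paste(key, format(p, digits = 17, scientific = FALSE,
                               trim = TRUE), sep = sep), con)
  invisible(path)
}

#' @rdname write_joint_dist
#' @export
read_joint_dist <- function(path, sep = "\t") {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- sub("^#\\s*", "", lines[hdr])
  vline <- meta[startsWith(meta, "variables:")]
  if (!length(vline)) stop("missing '# variables:' header")
  vars <- strsplit(sub("^variables:\\s*", "", vline[1]), ";", fixed = TRUE)[[1]]
  supports <- lapply(vars, function(v) {
    sl <- meta[startsWith(meta, paste0("support ", v, ":"))]
    if (!length(sl)) stop("missing support header for '", v, "'")
    strsplit(sub("^support [^:]+:\\s*", "", sl[1]), ";", fixed = TRUE)[[1]]
  })
  names(supports) <- vars
  body <- strsplit(lines[!hdr & nzchar(lines)], sep, fixed = TRUE)
  keys <- vapply(body, `[`, character(1), 1)
  p <- as.numeric(vapply(body, `[`, character(1), 2))
  arr <- array(0, dim = unname(lengths(supports)), dimnames = supports)
  parts <- strsplit(keys, ";", fixed = TRUE)
  if (any(lengths(parts) != length(vars)))
    stop("outcome keys must have one category per variable")
  idx <- mapply(function(part) {
    m <- mapply(match, part, supports)
    if (anyNA(m)) stop("outcome label outside declared support")
    m
  }, parts)
  arr[t(idx)] <- p
  joint_dist(arr)
}
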