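#' Williams-Beer partial information decomposition (Imin)
#'
#' Functions implementing the original partial information decomposition:
#' the specific information a source carries about a particular target
#' state, the Imin redundancy of a collection of sources (the expected
#' minimum specific information), the antichain lattice of source
#' collections, and the Moebius inversion that turns redundancies into
#' non-overlapping partial-information atoms.
#'
#' @name pid_lattice
NULL

# canonical form of a collection of integer source-groups:
# elements sorted within groups, groups sorted, stored as list of integer vecs
canonical_collection <- function(groups) {
  groups <- lapply(groups, function(g) sort(unique(as.integer(g))))
  key <- vapply(groups, paste, character(1), collapse = "")
  groups[order(nchar(key), key)]
}

collection_label <- function(groups) {
  groups <- canonical_collection(groups)
  paste(vapply(groups, function(g)
    paste0("{", paste(g, collapse = ""), "}"), character(1)), collapse = "")
}

is_antichain <- function(groups) {
  n <- length(groups)
  if (!n) return(FALSE)
  if (n == 1) return(TRUE)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && all(groups[[i]] %in% groups[[j]])) return(FALSE)
  }
  TRUE
}

# alpha precedes-or-equals beta: every group of beta contains some group of alpha
collection_leq <- function(alpha, beta) {
  all(vapply(beta, function(B)
    any(vapply(alpha, function(A) all(A %in% B), logical(1))), logical(1)))
}

#' Antichain lattice of source collections
#'
#' Enumerates all collections of non-empty subsets of `n_sources` sources
#' such that no subset in a collection contains another (the antichain
#' property), together with the partial order `alpha <= beta` iff every
#' group in `beta` contains some group in `alpha`, and each node's set of
#' strictly lower nodes. This is the structure on which the Imin
#' redundancy is Moebius-inverted: 4 nodes for two sources, 18 for three.
#'
#' @param n_sources 2 or 3.
#' @return an object of class `antichain_lattice`: list with `nodes`
#'   (list of collections, each a list of integer vectors), `labels`,
#'   and `down_sets` (per node, integer indices of strictly lower nodes),
#'   ordered bottom-up (every node appears after all nodes below it).
#' @export
build_lattice <- function(n_sources) {
  if (!n_sources %in% c(2L, 3L))
    stop("only 2- and 3-source lattices are supported")
  src <- seq_len(n_sources)
  subsets <- unlist(lapply(src, function(k)
    utils::combn(src, k, simplify = FALSE)), recursive = FALSE)
  m <- length(subsets)
  nodes <- list()
  for (mask in seq_len(2^m - 1)) {
    pick <- subsets[bitwAnd(mask, bitwShiftL(1, seq_len(m) - 1)) != 0]
    if (is_antichain(pick)) nodes[[length(nodes) + 1]] <- canonical_collection(pick)
  }
  k <- length(nodes)
  leq <- matrix(FALSE, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    leq[i, j] <- collection_leq(nodes[[i]], nodes[[j]])
  # bottom-up topological order by number of strictly-lower nodes
  below_count <- colSums(leq) - 1L
  ord <- order(below_count)
  nodes <- nodes[ord]
  leq <- leq[ord, ord, drop = FALSE]
  down_sets <- lapply(seq_len(k), function(j) setdiff(which(leq[, j]), j))
  structure(list(
    n_sources = n_sources,
    nodes = nodes,
    labels = vapply(nodes, collection_label, character(1)),
    down_sets = down_sets),
    class = "antichain_lattice")
}

#' @export
print.antichain_lattice <- function(x, ...) {
  cat("Antichain lattice over", x$n_sources, "sources:",
      length(x$nodes), "nodes\n")
  cat(paste(x$labels, collapse = "  "), "\n")
  invisible(x)
}

#' Specific information of a source about one target state
#'
#' The information a source (macro-)variable carries about the event
#' `target = target_value`: `sum_s P(s | y) * (log2 P(y | s) - log2 P(y))`.
#' Its expectation over target states equals the mutual information
#' between source and target.
#'
#' @param dist a [joint_dist()].
#' @param source,target disjoint character vectors of variable names.
#' @param target_value a vector of category labels, one per target
#'   variable (a single label if the target is one variable); the joint
#'   target state must have positive probability.
#' @return specific information in bits.
#' @export
specific_information <- function(dist, source, target, target_value) {
  source <- check_vars(dist, source, "source")
  target <- check_vars(dist, target, "target")
  if (length(intersect(source, target)))
    stop("source and target must be disjoint")
  m <- marginal(dist, c(source, target))
  # arrange as matrix: rows = source states, cols = target states
  dn <- dimnames(m)
  src_in <- intersect(names(dn), source)
  tgt_in <- intersect(names(dn), target)
  perm <- match(c(src_in, tgt_in), names(dn))
  m <- aperm(m, perm)
  ns <- prod(lengths(dn[src_in]))
  nt <- prod(lengths(dn[tgt_in]))
  sm <- matrix(as.vector(m), ns, nt)
  tgt_states <- expand.grid(dn[tgt_in], KEEP.OUT.ATTRS = FALSE,
                            stringsAsFactors = FALSE)
  target_value <- as.character(target_value)
  if (length(target_value) != length(tgt_in))
    stop("target_value must give one label per target variable")
  # match in the order the target variables appear in the distribution
  tv <- target_value[match(tgt_in, target)]
  col <- which(Reduce(`&`, lapply(seq_along(tgt_in), function(i)
    tgt_states[[i]] == tv[i])))
  if (!length(col)) stop("target_value outside the target support")
  p_sy <- sm[, col]
  p_y <- sum(p_sy)
  if (p_y <= 0) stop("target_value has zero probability")
  p_s <- rowSums(sm)
  keep <- p_sy > 0
  sum((p_sy[keep] / p_y) *
        (log2(p_sy[keep] / p_s[keep]) - log2(p_y)))
}

#' Imin redundancy of a collection of sources about a target
#'
#' The expected (over target states) minimum, across the groups of the
#' collection, of the specific information each group carries about that
#' state. For a single-group collection this reduces to the plain mutual
#' information between the group and the target.
#'
#' @inheritParams specific_information
#' @param collection list of character vectors (variable groups) forming
#'   an antichain: no group's variable set may contain another's.
#' @return redundancy in bits.
#' @export
imin_redundancy <- function(dist, collection, target) {
  if (!is.list(collection)) collection <- list(collection)
  collection <- lapply(collection, check_vars, dist = dist, what = "group")
  target <- check_vars(dist, target, "target")
  for (g in collection)
    if (length(intersect(g, target)))
      stop("target variable inside a source group")
  idx <- lapply(collection, function(g) which(dist$variables %in% g))
  if (!is_antichain(idx))
    stop("collection is not an antichain of variable groups")
  tgt_m <- marginal(dist, target)
  tgt_states <- expand.grid(dimnames(tgt_m), KEEP.OUT.ATTRS = FALSE,
                            stringsAsFactors = FALSE)
  p_y <- as.vector(tgt_m)
  total <- 0
  for (i in seq_along(p_y)) {
    if (p_y[i] <= 0) next
    spec <- vapply(collection, function(g)
      specific_information(dist, g, target, unlist(tgt_states[i, ])),
      numeric(1))
    total <- total + p_y[i] * min(spec)
  }
  total
}

new_pid_result <- function(joint_mi, marginal_mi, atoms, nodes, method,
                           sources, target) {
  fractions <- if (joint_mi > 1e-12) atoms / joint_mi else
    stats::setNames(rep(NA_real_, length(atoms)), names(atoms))
  structure(list(
    joint_mi = joint_mi,
    marginal_mi = marginal_mi,
    atoms = atoms,
    fractions = fractions,
    nodes = nodes,
    method = method,
    sources = sources,
    target = target),
    class = "pid_result")
}

#' @export
print.pid_result <- function(x, digits = 6, ...) {
  cat("Partial information decomposition (", x$method, ")\n", sep = "")
  cat("  sources:", paste(vapply(x$sources, paste, character(1),
                                 collapse = ","), collapse = " | "),
      " target:", paste(x$target, collapse = ","), "\n")
  cat("  joint MI:", format(x$joint_mi, digits = digits), "bits\n")
  tab <- data.frame(atom = names(x$atoms),
                    bits = round(unname(x$atoms), digits),
                    fraction = round(unname(x$fractions), digits))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Partial information decomposition with the Imin redundancy function
#'
#' Evaluates the Imin redundancy on every node of the antichain lattice
#' and Moebius-inverts bottom-up (`pi(alpha) = Imin(alpha) -
#' sum(pi(beta), beta < alpha)`) to obtain the partial-information atoms.
#' For two sources the familiar four atoms are labelled `{1}{2}`
#' (redundant), `{1}`, `{2}` (unique) and `{12}` (synergistic); the
#' three-source lattice has 18 atoms. Atom values within `1e-12` below
#' zero are clamped to zero (floating-point guard only).
#'
#' @param dist a [joint_dist()].
#' @param sources list of 2 or 3 disjoint character vectors.
#' @param target character vector, disjoint from all sources.
#' @param route for two sources, `"mobius"` (lattice inversion, default)
#'   or `"algebraic"` (redundancy from Imin, unique and synergy by
#'   subtraction from the marginal and joint mutual informations); the
#'   two agree to numerical precision.
#' @return a `pid_result`: joint and per-source mutual informations,
#'   named atom vector (bits), fractions of the joint MI (set to `NA`
#'   when the joint MI is below `1e-12`), and the node structure used.
#' @export
pid_imin <- function(dist, sources, target, route = c("mobius", "algebraic")) {
  route <- match.arg(route)
  if (!is.list(sources)) sources <- as.list(sources)
  n <- length(sources)
  if (!n %in% c(2L, 3L)) stop("pid_imin supports 2 or 3 sources")
  sources <- lapply(sources, check_vars, dist = dist, what = "source")
  if (anyDuplicated(unlist(sources))) stop("sources must be pairwise disjoint")
  target <- check_vars(dist, target, "target")
  lat <- build_lattice(n)
  group_vars <- function(g) unlist(sources[g])
  joint_mi <- mutual_information(dist, unlist(sources), target)
  marginal_mi <- vapply(sources, function(s)
    mutual_information(dist, s, target), numeric(1))
  names(marginal_mi) <- vapply(seq_len(n), function(i)
    collection_label(list(i)), character(1))
  if (entropy(dist, target) < 1e-12) {
    warning("target is (nearly) constant; all atoms are 0")
    atoms <- stats::setNames(rep(0, length(lat$nodes)), lat$labels)
    return(new_pid_result(0, marginal_mi * 0, atoms, lat$nodes, "imin",
                          sources, target))
  }
  if (route == "algebraic" && n == 2L) {
    red <- imin_redundancy(dist, list(group_vars(1), group_vars(2)), target)
    unq1 <- marginal_mi[1] - red
    unq2 <- marginal_mi[2] - red
    syn <- joint_mi - red - unq1 - unq2
    atoms <- c(red, unname(unq1), unname(unq2), syn)
    names(atoms) <- c("{1}{2}", "{1}", "{2}", "{12}")
    atoms <- atoms[lat$labels]
  } else {
    imin_vals <- vapply(lat$nodes, function(node)
      imin_redundancy(dist, lapply(node, group_vars), target), numeric(1))
    atoms <- numeric(length(lat$nodes))
    for (j in seq_along(lat$nodes))
      atoms[j] <- imin_vals[j] - sum(atoms[lat$down_sets[[j]]])
    names(atoms) <- lat$labels
  }
  atoms[atoms < 0 & atoms >= -1e-12] <- 0
  new_pid_result(joint_mi, marginal_mi, atoms, lat$nodes, "imin",
                 sources, target)
}

#' Aggregate PID atoms into interpretable categories
#'
#' Collections made of two or more singleton sources (`{1}{2}`,
#' `{1}{2}{3}`, ...) are purely redundant; single singletons (`{1}`) are
#' unique; a single multi-source group (`{12}`, `{123}`) is purely
#' synergistic; everything else (mixed collections such as `{1}{23}`)
#' counts as exotic higher-order structure. For two sources the exotic
#' total is exactly zero (no mixed nodes exist).
#'
#' @param result a `pid_result`.
#' @return an object of class `atom_classification`: per-atom categories
#'   plus per-category totals in bits and as fractions of the joint MI.
#' @export
classify_atoms <- function(result) {
  stopifnot(inherits(result, "pid_result"))
  cat_of <- function(node) {
    sizes <- lengths(node)
    if (length(node) >= 2 && all(sizes == 1)) "redundant"
    else if (length(node) == 1 && sizes == 1) "unique"
    else if (length(node) == 1 && sizes >= 2) "synergistic"
    else "exotic"
  }
  categories <- vapply(result$nodes, cat_of, character(1))
  lv <- c("redundant", "unique", "synergistic", "exotic")
  bits <- vapply(lv, function(l) sum(result$atoms[categories == l]),
                 numeric(1))
  fractions <- if (result$joint_mi > 1e-12) bits / result$joint_mi else
    stats::setNames(rep(NA_real_, 4), lv)
  structure(list(categories = stats::setNames(categories, names(result$atoms)),
                 bits = bits, fractions = fractions,
                 joint_mi = result$joint_mi),
            class = "atom_classification")
}

#' @export
print.atom_classification <- function(x, digits = 6, ...) {
  cat("PID atom categories (joint MI =",
      format(x$joint_mi, digits = digits), "bits)\n")
  tab <- data.frame(category = names(x$bits),
                    bits = round(unname(x$bits), digits),
                    fraction = round(unname(x$fractions), digits))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Serialize a PID result to a flat key-value text file
#'
#' One line per atom: node label in bracket notation, value in bits, and
#' fraction of the joint mutual information, tab-separated; header lines
#' carry the method, joint MI and marginal MIs.
#'
#' @param result a `pid_result`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_pid_result <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# method: ", result$method),
    paste0("# joint_mi: ", format(result$joint_mi, digits = 17)),
    paste0("# marginal_mi: ",
           paste(names(result$marginal_mi),
                 format(result$marginal_mi, digits = 17),
                 sep = "=", collapse = " "))), con)
  writeLines(paste(names(result$atoms),
                   format(unname(result$atoms), digits = 17),
                   format(unname(result$fractions), digits = 17),
                   sep = "\t"), con)
  invisible(path)
}
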