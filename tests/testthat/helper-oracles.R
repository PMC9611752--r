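# Independent brute-force oracles: everything here works by enumerating
# the full outcome set with plain loops / data.frame aggregation, never
# through the package's marginalisation or solver code paths.

# full enumeration of a joint_dist as (outcome data.frame, probability)
enumerate_dist <- function(dist) {
  grid <- expand.grid(dist$supports, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid$p <- as.vector(dist$prob)
  grid
}

oracle_marginal_df <- function(dist, vars) {
  g <- enumerate_dist(dist)
  key <- do.call(paste, c(g[vars], sep = "\r"))
  agg <- tapply(g$p, key, sum)
  data.frame(key = names(agg), p = as.vector(agg), stringsAsFactors = FALSE)
}

oracle_entropy <- function(dist, vars) {
  p <- oracle_marginal_df(dist, vars)$p
  p <- p[p > 0]
  -sum(p * log2(p))
}

oracle_mi <- function(dist, a, b) {
  oracle_entropy(dist, a) + oracle_entropy(dist, b) -
    oracle_entropy(dist, c(a, b))
}

# specific information by direct summation over source states
oracle_specific_information <- function(dist, source, target, y) {
  g <- enumerate_dist(dist)
  ty <- do.call(paste, c(g[target], sep = "\r"))
  yk <- paste(y, collapse = "\r")
  sk <- do.call(paste, c(g[source], sep = "\r"))
  p_y <- sum(g$p[ty == yk])
  total <- 0
  for (s in unique(sk)) {
    p_s <- sum(g$p[sk == s])
    p_sy <- sum(g$p[sk == s & ty == yk])
    if (p_sy > 0)
      total <- total + (p_sy / p_y) * (log2(p_sy / p_s) - log2(p_y))
  }
  total
}

oracle_imin <- function(dist, collection, target) {
  g <- enumerate_dist(dist)
  ty <- do.call(paste, c(g[target], sep = "\r"))
  total <- 0
  for (yk in unique(ty)) {
    p_y <- sum(g$p[ty == yk])
    if (p_y <= 0) next
    yv <- strsplit(yk, "\r", fixed = TRUE)[[1]]
    total <- total + p_y * min(vapply(collection, function(grp)
      oracle_specific_information(dist, grp, target, yv), numeric(1)))
  }
  total
}

# two-source decomposition from the redundancy by plain algebra
oracle_pid2 <- function(dist, s1, s2, target) {
  red <- oracle_imin(dist, list(s1, s2), target)
  i1 <- oracle_mi(dist, s1, target)
  i2 <- oracle_mi(dist, s2, target)
  joint <- oracle_mi(dist, c(s1, s2), target)
  c(red = red, unq1 = i1 - red, unq2 = i2 - red,
    syn = joint - i1 - i2 + red)
}

# conditional mutual information I(X1; Y | X2) of a 3-d pmf array, by loops
oracle_cmi <- function(q) {
  d <- dim(q)
  total <- 0
  for (x2 in seq_len(d[2])) {
    p2 <- sum(q[, x2, ])
    if (p2 <= 0) next
    for (x1 in seq_len(d[1])) for (y in seq_len(d[3])) {
      v <- q[x1, x2, y]
      if (v <= 0) next
      total <- total + v * log2(v * p2 / (sum(q[x1, x2, ]) * sum(q[, x2, y])))
    }
  }
  total
}

# dense grid + refinement search for the optimization-based unique
# information over the feasible polytope (preserve both source-target
# marginals); meant for small (2x2x2-ish) supports only
oracle_broja_unique <- function(p, grid_n = 41, rounds = 3) {
  d <- dim(p)
  m1y <- apply(p, c(1, 3), sum)
  m2y <- apply(p, c(2, 3), sum)
  cells <- expand.grid(x1 = seq_len(d[1]), x2 = seq_len(d[2]),
                       y = seq_len(d[3]))
  ok <- m1y[cbind(cells$x1, cells$y)] > 0 & m2y[cbind(cells$x2, cells$y)] > 0
  A <- rbind(
    t(vapply(which(m1y > 0), function(k) {
      i <- (k - 1) %% d[1] + 1; y <- (k - 1) %/% d[1] + 1
      as.numeric(cells$x1[ok] == i & cells$y[ok] == y)
    }, numeric(sum(ok)))),
    t(vapply(which(m2y > 0), function(k) {
      i <- (k - 1) %% d[2] + 1; y <- (k - 1) %/% d[2] + 1
      as.numeric(cells$x2[ok] == i & cells$y[ok] == y)
    }, numeric(sum(ok)))))
  q_emp <- as.vector(p)[ok]
  sv <- svd(A, nu = 0, nv = ncol(A))
  nullity <- sum(c(sv$d, rep(0, ncol(A) - length(sv$d))) < 1e-10)
  to_arr <- function(q) {
    full <- numeric(nrow(cells)); full[ok] <- q
    array(full, dim = d)
  }
  if (nullity == 0) return(oracle_cmi(to_arr(q_emp)))
  N <- sv$v[, (ncol(A) - nullity + 1):ncol(A), drop = FALSE]
  # per-axis feasible range of q_emp + t * N_i >= 0 (bounding box of the
  # feasible polytope slice through the empirical point)
  ranges <- vapply(seq_len(nullity), function(i) {
    v <- N[, i]
    lo <- suppressWarnings(max(-q_emp[v > 1e-14] / v[v > 1e-14], -50))
    hi <- suppressWarnings(min(-q_emp[v < -1e-14] / v[v < -1e-14], 50))
    c(lo, hi)
  }, numeric(2))
  centre <- rep(0, nullity)
  widths <- (ranges[2, ] - ranges[1, ]) / 2
  centre <- colMeans(ranges)
  best <- oracle_cmi(to_arr(q_emp))
  best_th <- rep(0, nullity)
  for (r in seq_len(rounds)) {
    axes <- lapply(seq_len(nullity), function(i)
      seq(centre[i] - widths[i], centre[i] + widths[i],
          length.out = grid_n))
    th_grid <- as.matrix(expand.grid(axes))
    for (row in seq_len(nrow(th_grid))) {
      q <- q_emp + as.vector(N %*% th_grid[row, ])
      if (any(q < -1e-12)) next
      val <- oracle_cmi(to_arr(pmax(q, 0)))
      if (val < best) { best <- val; best_th <- th_grid[row, ] }
    }
    centre <- best_th
    widths <- widths * 3 / grid_n
  }
  best
}

# plain (x1, x2, y) pmf array of a joint_dist whose variables are
# already ordered (source1, source2, target)
collapse_broja_array <- function(dist) {
  stopifnot(length(dist$variables) == 3)
  dist$prob
}

# random categorical joint distribution with named variables
random_dist <- function(dims, vars = paste0("v", seq_along(dims)),
                        zero_frac = 0) {
  p <- stats::rgamma(prod(dims), 1)
  if (zero_frac > 0)
    p[sample.int(length(p), floor(zero_frac * length(p)))] <- 0
  if (sum(p) == 0) p[1] <- 1
  supports <- lapply(dims, function(k) as.character(seq_len(k)))
  names(supports) <- vars
  arr <- array(p / sum(p), dim = dims, dimnames = supports)
  joint_dist(arr)
}

# small balanced census-like table with two records per identity cell
tiny_balanced_table <- function() {
  df <- expand.grid(race = c("White", "Black"), sex = c("Male", "Female"),
                    rep = 1:2, stringsAsFactors = FALSE)
  df$age <- 40
  df$nativity <- "Native"
  df$employment <- "Full-time"
  df$income <- c(80000, 40000, 50000, 20000, 90000, 45000, 52000, 30000)
  df$health <- c(1, 3, 2, 5, 2, 3, 2, 4)
  person_table(df[c("race", "sex", "age", "nativity", "employment",
                    "income", "health")])
}
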