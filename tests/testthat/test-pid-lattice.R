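test_that("specific information matches direct evaluation", {
  # independent source: zero for every target state
  px <- c(0.3, 0.7); py <- c(0.6, 0.4)
  ind <- joint_dist(array(outer(px, py), dim = c(2, 2),
                          dimnames = list(x = c("0", "1"), y = c("0", "1"))))
  expect_equal(specific_information(ind, "x", "y", "0"), 0, tolerance = 1e-12)
  expect_equal(specific_information(ind, "x", "y", "1"), 0, tolerance = 1e-12)

  copy <- joint_dist(array(c(0.5, 0, 0, 0.5), dim = c(2, 2),
                           dimnames = list(x = c("0", "1"), y = c("0", "1"))))
  expect_equal(specific_information(copy, "x", "y", "0"), 1, tolerance = 1e-12)

  andg <- gate_distribution("and")
  for (y in c("0", "1"))
    expect_equal(specific_information(andg, "x1", "y", y),
                 oracle_specific_information(andg, "x1", "y", y),
                 tolerance = 1e-12)
  # expectation over target states recovers the mutual information
  set.seed(3)
  d <- random_dist(c(3, 4), vars = c("s", "t"))
  tm <- marginal(d, "t")
  expect_equal(sum(vapply(seq_along(tm), function(i)
    tm[i] * specific_information(d, "s", "t", dimnames(tm)[[1]][i]),
    numeric(1))),
    mutual_information(d, "s", "t"), tolerance = 1e-9)
  expect_error(specific_information(copy, "x", "y", "zzz"), "support")
})

test_that("Imin redundancy: degenerate min, duplicated sources, AND gate", {
  andg <- gate_distribution("and")
  expect_equal(imin_redundancy(andg, list("x1"), "y"),
               mutual_information(andg, "x1", "y"), tolerance = 1e-12)
  dup <- gate_distribution("redundant_copy")
  expect_equal(imin_redundancy(dup, list("x1", "x2"), "y"), 1,
               tolerance = 1e-12)
  # closed form for the uniform AND gate
  and_red <- 0.75 * (2 / 3 * log2(4 / 3) + 1 / 3 * log2(2 / 3)) + 0.25 * 1
  expect_equal(imin_redundancy(andg, list("x1", "x2"), "y"), and_red,
               tolerance = 1e-12)
  expect_equal(oracle_imin(andg, list("x1", "x2"), "y"), and_red,
               tolerance = 1e-12)
  expect_error(imin_redundancy(andg, list("x1", c("x2", "y")), "y"),
               "target variable inside")
})

test_that("antichain lattice has the textbook structure", {
  lat2 <- build_lattice(2)
  expect_length(lat2$nodes, 4)
  expect_setequal(lat2$labels, c("{1}{2}", "{1}", "{2}", "{12}"))
  # bottom {1}{2} below both singletons, which sit below the top {12}
  idx <- function(l) which(lat2$labels == l)
  expect_true(idx("{1}{2}") %in% lat2$down_sets[[idx("{1}")]])
  expect_true(idx("{1}{2}") %in% lat2$down_sets[[idx("{2}")]])
  expect_setequal(lat2$down_sets[[idx("{12}")]],
                  c(idx("{1}{2}"), idx("{1}"), idx("{2}")))

  lat3 <- build_lattice(3)
  expect_length(lat3$nodes, 18)
  # stored order is antisymmetric and transitive
  leq <- vapply(seq_len(18), function(j)
    vapply(seq_len(18), function(i)
      i == j || i %in% lat3$down_sets[[j]], logical(1)), logical(18))
  for (i in 1:18) for (j in 1:18) {
    if (i != j && leq[i, j]) expect_false(leq[j, i])
    for (k in 1:18) if (leq[i, j] && leq[j, k]) expect_true(leq[i, k])
  }
  expect_error(build_lattice(4), "supported")
})

test_that("pid_imin reproduces canonical gates exactly", {
  xor <- pid_imin(gate_distribution("xor"), list("x1", "x2"), "y")
  expect_equal(unname(xor$atoms[c("{1}{2}", "{1}", "{2}", "{12}")]),
               c(0, 0, 0, 1), tolerance = 1e-12)

  # second source an exact relabelling of the first, target = first
  arr <- array(0, dim = c(2, 2, 2),
               dimnames = list(x1 = c("0", "1"), x2 = c("b", "a"),
                               y = c("0", "1")))
  arr["0", "b", "0"] <- 0.5; arr["1", "a", "1"] <- 0.5
  rel <- pid_imin(joint_dist(arr), list("x1", "x2"), "y")
  expect_equal(unname(rel$atoms[c("{1}{2}", "{1}", "{2}", "{12}")]),
               c(1, 0, 0, 0), tolerance = 1e-12)

  andr <- pid_imin(gate_distribution("and"), list("x1", "x2"), "y")
  and_red <- 0.75 * (2 / 3 * log2(4 / 3) + 1 / 3 * log2(2 / 3)) + 0.25
  h14 <- -(0.25 * log2(0.25) + 0.75 * log2(0.75))
  expect_equal(unname(andr$atoms[c("{1}{2}", "{1}", "{2}", "{12}")]),
               c(and_red, 0, 0, h14 - and_red), tolerance = 1e-12)
})

test_that("Moebius and algebraic routes agree; identities hold on random draws", {
  set.seed(17)
  for (k in 1:40) {
    dims <- c(sample(2:4, 1), sample(2:4, 1), sample(2:5, 1))
    d <- random_dist(dims, vars = c("x1", "x2", "y"),
                     zero_frac = sample(c(0, 0.2), 1))
    rm_ <- pid_imin(d, list("x1", "x2"), "y")
    ra <- pid_imin(d, list("x1", "x2"), "y", route = "algebraic")
    expect_equal(rm_$atoms, ra$atoms, tolerance = 1e-9)
    # self-consistency and nonnegativity
    expect_equal(sum(rm_$atoms), rm_$joint_mi, tolerance = 1e-6)
    expect_equal(rm_$atoms[["{1}{2}"]] + rm_$atoms[["{1}"]],
                 rm_$marginal_mi[["{1}"]], tolerance = 1e-6)
    expect_equal(rm_$atoms[["{1}{2}"]] + rm_$atoms[["{2}"]],
                 rm_$marginal_mi[["{2}"]], tolerance = 1e-6)
    expect_true(all(rm_$atoms >= -1e-9))
    # whole-minus-sum equals Syn - Red
    expect_equal(whole_minus_sum(d, list("x1", "x2"), "y"),
                 rm_$atoms[["{12}"]] - rm_$atoms[["{1}{2}"]],
                 tolerance = 1e-9)
    # the full decomposition matches the brute-force oracle
    o <- oracle_pid2(d, "x1", "x2", "y")
    expect_equal(unname(rm_$atoms[c("{1}{2}", "{1}", "{2}", "{12}")]),
                 unname(o), tolerance = 1e-9)
  }
})

test_that("constant target yields zero atoms with a warning", {
  arr <- array(c(0.2, 0.3, 0.1, 0.4), dim = c(2, 2, 1),
               dimnames = list(x1 = c("0", "1"), x2 = c("0", "1"), y = "k"))
  d <- joint_dist(arr)
  expect_warning(r <- pid_imin(d, list("x1", "x2"), "y"), "constant")
  expect_true(all(r$atoms == 0))
  expect_true(all(is.na(r$fractions)))
})

test_that("atom classification buckets the lattice correctly", {
  # two sources: no exotic nodes exist
  r2 <- pid_imin(gate_distribution("and"), list("x1", "x2"), "y")
  cl2 <- classify_atoms(r2)
  expect_equal(unname(cl2$bits[["exotic"]]), 0)
  expect_equal(sum(cl2$bits), r2$joint_mi, tolerance = 1e-9)

  # three sources: 4 redundant, 3 unique, 4 synergistic, 7 exotic nodes
  p3 <- gate_distribution("parity3")
  r3 <- pid_imin(p3, list("x1", "x2", "x3"), "y")
  cl3 <- classify_atoms(r3)
  expect_equal(as.vector(table(cl3$categories)[c(
    "redundant", "unique", "synergistic", "exotic")]), c(4L, 3L, 4L, 7L))
  # three-input parity: all information is pure three-way synergy
  expect_equal(unname(cl3$bits[["synergistic"]]), 1, tolerance = 1e-9)
  expect_equal(unname(r3$atoms[["{123}"]]), 1, tolerance = 1e-9)
  expect_equal(sum(r3$atoms), r3$joint_mi, tolerance = 1e-6)
})

test_that("PID results serialize to the flat key-value format", {
  r <- pid_imin(gate_distribution("and"), list("x1", "x2"), "y")
  path <- withr::local_tempfile(fileext = ".txt")
  write_pid_result(r, path)
  lines <- readLines(path)
  expect_true(any(grepl("^# method: imin", lines)))
  body <- strsplit(grep("^#", lines, invert = TRUE, value = TRUE), "\t")
  expect_setequal(vapply(body, `[`, character(1), 1),
                  c("{1}{2}", "{1}", "{2}", "{12}"))
  vals <- as.numeric(vapply(body, `[`, character(1), 2))
  expect_equal(sum(vals), r$joint_mi, tolerance = 1e-9)
})
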