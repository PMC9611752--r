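#' Canonical logic-gate distributions
#'
#' Exact joint distributions of the standard test battery for partial
#' information decompositions: uniform independent binary inputs with a
#' deterministic target. `xor` (pure synergy), `and`, `copy_x1` (the
#' target copies the first source, the second is an independent coin;
#' pure unique information), `redundant_copy` (both sources and the
#' target are the same uniform bit; pure redundancy) and `parity3`
#' (three-input XOR; pure three-way synergy).
#'
#' @param name one of `"xor"`, `"and"`, `"copy_x1"`, `"redundant_copy"`,
#'   `"parity3"`.
#' @return a [joint_dist()] over sources `x1`, `x2` (and `x3` for
#'   `parity3`) and target `y`, with exact rational probabilities.
#' @export
gate_distribution <- function(name = c("xor", "and", "copy_x1",
                                       "redundant_copy", "parity3")) {
  name <- match.arg(name)
  b <- c("0", "1")
  if (name == "parity3") {
    arr <- array(0, dim = c(2, 2, 2, 2),
                 dimnames = list(x1 = b, x2 = b, x3 = b, y = b))
    for (i in 0:1) for (j in 0:1) for (k in 0:1)
      arr[i + 1, j + 1, k + 1, ((i + j + k) %% 2) + 1] <- 1 / 8
    return(joint_dist(arr))
  }
  if (name == "redundant_copy") {
    arr <- array(0, dim = c(2, 2, 2),
                 dimnames = list(x1 = b, x2 = b, y = b))
    arr[1, 1, 1] <- 0.5
    arr[2, 2, 2] <- 0.5
    return(joint_dist(arr))
  }
  f <- switch(name,
              xor = function(i, j) (i + j) %% 2,
              and = function(i, j) i * j,
              copy_x1 = function(i, j) i)
  arr <- array(0, dim = c(2, 2, 2),
               dimnames = list(x1 = b, x2 = b, y = b))
  for (i in 0:1) for (j in 0:1)
    arr[i + 1, j + 1, f(i, j) + 1] <- 1 / 4
  joint_dist(arr)
}
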