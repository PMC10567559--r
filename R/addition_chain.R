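# Minimal addition chains: the homopolymer assembly index. A chain
# 1 = c0 < c1 < ... < cr = n with every ck a sum of two earlier terms is an
# assembly pathway for a homopolymer of length n; the minimal r is its
# assembly index.

.chain_cache <- new.env(parent = emptyenv())

#' Minimal addition chain for a homopolymer length
#'
#' Computes the assembly index of a homopolymer of length `n`: the minimal
#' number of additions `i + j` (with `i`, `j` already in the chain, starting
#' from 1) needed to reach `n`. Exact iterative-deepening search up to
#' `exact_limit`; beyond it the binary (double-and-add) chain is returned and
#' flagged approximate. The exact search returns the lexicographically
#' smallest minimal chain, so results are deterministic.
#'
#' @param n Positive integer (may exceed integer range; lengths are handled
#'   as doubles).
#' @param exact_limit Largest `n` searched exactly (default `2^16`).
#' @param allow_approx If `FALSE`, lengths above `exact_limit` are refused
#'   with an error instead of falling back to the binary chain.
#' @return List with `index`, `chain` (data frame with columns `value`, `i`,
#'   `j`: each chain element and its two summands) and `approximate`.
#' @examples
#' addition_chain_min(15)$index  # 5
#' @export
addition_chain_min <- function(n, exact_limit = 2^16, allow_approx = TRUE) {
  if (length(n) != 1L || is.na(n) || n < 1 || n != floor(n))
    stop("homopolymer length must be a single positive integer")
  if (n <= exact_limit) {
    key <- sprintf("%.0f", n)
    hit <- .chain_cache[[key]]
    if (!is.null(hit)) return(hit)
    r <- .addition_chain_exact(n)
    out <- list(index = r$index,
                chain = data.frame(value = r$value, i = r$i, j = r$j),
                approximate = FALSE)
    .chain_cache[[key]] <- out
    return(out)
  }
  if (!allow_approx)
    stop(sprintf("length %s exceeds the exact-search limit %s; no exact chain computed",
                 format(n), format(exact_limit)))
  ch <- binary_chain(n)
  list(index = nrow(ch), chain = ch, approximate = TRUE)
}

# Double-and-add chain from the binary expansion of n; length
# floor(log2 n) + popcount(n) - 1. Works on doubles (deterministic, though
# bits beyond 2^53 reflect the rounded double).
binary_chain <- function(n) {
  bits <- numeric(0)
  x <- n
  while (x >= 1) {
    bits <- c(x - 2 * floor(x / 2), bits)  # low bit last in n's expansion
    x <- floor(x / 2)
  }
  v <- 1
  value <- i <- j <- numeric(0)
  for (b in bits[-1]) {
    value <- c(value, 2 * v); i <- c(i, v); j <- c(j, v); v <- 2 * v
    if (b == 1) { value <- c(value, v + 1); i <- c(i, v); j <- c(j, 1); v <- v + 1 }
  }
  data.frame(value = value, i = i, j = j)
}
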