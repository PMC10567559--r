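# Exact string assembly index. A minimal pathway for a string only ever
# constructs substrings of the target (anything else can never contribute
# characters to it), so the search runs top-down over substring goals: the
# target must be split into two parts, each part either elementary (one
# character), already scheduled for construction, or a new goal. The assembly
# index is the minimal number of distinct constructed substrings; iterative
# deepening on that count with memoized failure states guarantees minimality
# with bounded memory.

#' Exact assembly index of a string
#'
#' Minimal number of recursive join (concatenation) steps needed to build a
#' string from single characters, where every intermediate, once built, can
#' be reused at no extra cost. Returns the index together with a shortest
#' assembly pathway.
#'
#' @param s A character string or a string `assembly_object`.
#' @param max_size Exact-search limit on the string length (default 25).
#'   Longer strings are refused: no silent heuristic fallback exists.
#' @return List with `index` (integer) and `pathway` (an
#'   [`assembly_pathway`][replay_pathway]).
#' @examples
#' assembly_index_string("ABRACADABRA")$index  # 7
#' @export
assembly_index_string <- function(s, max_size = 25) {
  obj <- if (inherits(s, "assembly_object")) s else canonicalize(s, "string")
  if (obj$kind != "string") stop("assembly_index_string expects a string object")
  n <- obj$size
  if (n > max_size)
    stop(sprintf(paste0("string of length %d exceeds the exact-search limit %d; ",
                        "refusing (bounds: %d..%d)"),
                 n, max_size, ceiling(log2(n)), n - 1))
  if (n == 1L) return(list(index = 0L, pathway = new_pathway(obj, list())))
  s <- obj$payload

  fail_memo <- new.env(parent = emptyenv())
  splits_of <- function(g) {
    ng <- nchar(g)
    k <- seq_len(ng - 1L)
    ord <- order(-pmin(k, ng - k), k)  # balanced splits first, deterministic
    lapply(k[ord], function(kk) c(substr(g, 1L, kk), substr(g, kk + 1L, ng)))
  }

  dfs <- function(goals, chosen, budget, acc) {
    if (length(goals) == 0L) return(acc)
    maxlen <- max(nchar(goals))
    if (length(goals) > budget || ceiling(log2(maxlen)) > budget) return(NULL)
    key <- paste0(budget, "|", paste(sort(goals), collapse = ","), "|",
                  paste(sort(chosen), collapse = ","))
    if (!is.null(fail_memo[[key]])) return(NULL)
    g <- goals[nchar(goals) == maxlen]
    g <- sort(g)[1L]
    rest <- setdiff(goals, g)
    chosen2 <- c(chosen, g)
    for (uv in splits_of(g)) {
      new_goals <- unique(c(rest, uv[nchar(uv) >= 2L]))
      new_goals <- setdiff(new_goals, chosen2)
      res <- dfs(new_goals, chosen2, budget - 1L,
                 c(acc, setNames(list(uv), g)))
      if (!is.null(res)) return(res)
    }
    fail_memo[[key]] <- TRUE
    NULL
  }

  for (budget in seq(ceiling(log2(n)), n - 1L)) {
    sol <- dfs(s, character(0), budget, list())
    if (!is.null(sol)) {
      prods <- names(sol)[order(nchar(names(sol)), names(sol))]
      steps <- lapply(prods, function(g) {
        uv <- sol[[g]]
        list(left = canonicalize(uv[1L], "string"),
             right = canonicalize(uv[2L], "string"),
             product = canonicalize(g, "string"))
      })
      return(list(index = length(steps), pathway = new_pathway(obj, steps)))
    }
  }
  stop("internal error: no pathway found within the trivial upper bound")
}
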