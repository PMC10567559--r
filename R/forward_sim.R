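# Forward assembly of linear homopolymers: starting from a single monomer in
# the assembly pool, joins add lengths. Undirected exploration combines two
# polymers drawn uniformly at random (with replacement) from the unique
# members of the pool; directed exploration always uses the most recently
# created polymer as one operand. The joint assembly space of a run is the
# union of (minimal) addition chains of all observed polymers; its
# exploration ratio (observed / total nodes) drops, and the maximum assembly
# index rises, when exploration is directed - the signal of selection.

#' Create a fresh assembly pool
#'
#' @return An `assembly_pool`: list with `members` (numeric lengths, always
#'   containing the monomer), `most_recent` (last newly created length) and
#'   `discovered` (first-discovery order).
#' @export
new_pool <- function() {
  structure(list(members = 1, most_recent = 1, discovered = 1),
            class = "assembly_pool")
}

#' One undirected assembly step
#'
#' Draws two members uniformly at random with replacement from the pool's
#' unique members and joins them; the product enters the pool if new.
#'
#' @param pool An `assembly_pool`.
#' @param weighted If `TRUE`, sampling is weighted by member lengths rather
#'   than uniform over unique member types (default `FALSE`).
#' @param replace Draw the two operands with replacement (default `TRUE`,
#'   so an object may join itself, enabling doubling). With `FALSE` the
#'   operands are distinct members; a single-member pool still self-joins,
#'   as nothing else is available.
#' @return The updated pool (never shrinks).
#' @export
step_undirected <- function(pool, weighted = FALSE, replace = TRUE) {
  m <- pool$members
  prob <- if (weighted) m / sum(m) else NULL
  idx <- if (!replace && length(m) == 1L) c(1L, 1L)  # only self-joining possible
         else sample.int(length(m), 2L, replace = replace, prob = prob)
  pool_add(pool, m[idx[1]] + m[idx[2]])
}

#' One directed assembly step
#'
#' Joins the most recently created polymer with a uniformly drawn pool
#' member; `most_recent` updates only when a genuinely new polymer is formed.
#'
#' @param pool An `assembly_pool`.
#' @return The updated pool.
#' @export
step_directed <- function(pool) {
  partner <- pool$members[sample.int(length(pool$members), 1L)]
  pool_add(pool, pool$most_recent + partner)
}

pool_add <- function(pool, len) {
  if (!(len %in% pool$members)) {
    pool$members <- c(pool$members, len)
    pool$discovered <- c(pool$discovered, len)
    pool$most_recent <- len
  }
  pool
}

#' Joint assembly space of a set of observed polymers
#'
#' The union of one minimal addition chain per observed length (deterministic
#' lexicographically-smallest tie-breaking), as a directed acyclic graph.
#' Nodes present in the observed set are flagged `observed`; chain-only nodes
#' are `contingent`. Lengths above `chain_limit` are refused unless
#' `allow_approx = TRUE`, in which case their binary double-and-add chain
#' stands in for the minimal chain (flagged in the result).
#'
#' @param observed Numeric vector of observed polymer lengths (must include
#'   every length whose pathway should contribute).
#' @param chain_limit Largest length given an exact minimal chain.
#' @param allow_approx Fall back to binary chains above `chain_limit`.
#' @return An `assembly_dag`: list with `nodes` (data frame: `length`,
#'   `flag`), `edges` (data frame: `from`, `to`, `left`, `right`), and
#'   `approximate` (were any chains binary fallbacks).
#' @examples
#' dag <- joint_assembly_space(c(1, 8))
#' exploration_ratio(dag)  # 0.5: nodes 1,2,4,8 with 2,4 contingent
#' @export
joint_assembly_space <- function(observed, chain_limit = 2^16, allow_approx = FALSE) {
  observed <- unique(as.numeric(observed))
  if (length(observed) == 0L) stop("empty observed set: no joint assembly space")
  if (any(observed < 1 | observed != floor(observed)))
    stop("observed lengths must be positive integers")
  over <- observed[observed > chain_limit]
  if (length(over) && !allow_approx)
    stop(sprintf("lengths above the exact-chain limit %s refused: %s",
                 format(chain_limit), paste(format(sort(over)), collapse = ", ")))
  nodes <- 1
  edges <- list()
  seen_edge <- new.env(parent = emptyenv())
  approx <- FALSE
  for (n in sort(observed)) {
    if (n == 1) next
    res <- addition_chain_min(n, exact_limit = chain_limit, allow_approx = TRUE)
    if (res$approximate) approx <- TRUE
    ch <- res$chain
    nodes <- c(nodes, ch$value)
    for (r in seq_len(nrow(ch))) {
      key <- sprintf("%.0f", ch$value[r])
      if (is.null(seen_edge[[key]])) {
        seen_edge[[key]] <- TRUE
        edges[[length(edges) + 1L]] <- c(ch$i[r], ch$value[r], ch$i[r], ch$j[r])
      }
    }
  }
  nodes <- sort(unique(nodes))
  em <- do.call(rbind, edges)
  edges_df <- if (is.null(em)) data.frame(from = numeric(0), to = numeric(0),
                                          left = numeric(0), right = numeric(0))
  else data.frame(from = em[, 1], to = em[, 2], left = em[, 3], right = em[, 4])
  structure(list(
    nodes = data.frame(length = nodes,
                       flag = ifelse(nodes %in% observed, "observed", "contingent")),
    edges = edges_df, approximate = approx), class = "assembly_dag")
}

#' @export
print.assembly_dag <- function(x, ...) {
  cat(sprintf("<assembly DAG> %d nodes (%d observed, %d contingent), %d join edges%s\n",
              nrow(x$nodes), sum(x$nodes$flag == "observed"),
              sum(x$nodes$flag == "contingent"), nrow(x$edges),
              if (x$approximate) " [some chains approximate]" else ""))
  invisible(x)
}

#' Exploration ratio of a joint assembly space
#'
#' Observed nodes divided by total (observed + contingent) nodes; values
#' near 1 mean the dynamics realized most of the space its products imply,
#' low values mean deep, selective exploration.
#'
#' @param dag An `assembly_dag` from [joint_assembly_space()].
#' @return Numeric in (0, 1].
#' @export
exploration_ratio <- function(dag) {
  stopifnot(inherits(dag, "assembly_dag"))
  if (nrow(dag$nodes) == 0L) stop("empty assembly space")
  sum(dag$nodes$flag == "observed") / nrow(dag$nodes)
}

#' Run a forward-assembly exploration experiment
#'
#' Repeats seeded undirected or directed runs, each of `steps` assembly
#' steps, and reports per-run and summary statistics: final pool size,
#' exploration ratio of the joint assembly space, maximum observed length,
#' and the maximum assembly index (minimal addition chain length of the
#' longest polymer, with the log2 approximation alongside).
#'
#' @param config A `sim_config` list: fields `mode` ("undirected" or
#'   "directed"), `steps`, `runs`, `seed`, and optionally `chain_limit`
#'   (exact-chain limit used for the joint space, default 1024).
#' @return List with `per_run` (data frame) and `summary` (mean and sd of
#'   each statistic); the seed is recorded in both.
#' @export
run_experiment <- function(config) {
  config <- validate_config(config)
  rows <- lapply(seq_len(config$runs), function(r) {
    run_seed <- (config$seed + r - 1L) %% .Machine$integer.max
    set.seed(run_seed)
    pool <- new_pool()
    for (s in seq_len(config$steps)) {
      pool <- if (config$mode == "directed") step_directed(pool)
              else step_undirected(pool)
    }
    dag <- joint_assembly_space(pool$members, chain_limit = config$chain_limit,
                                allow_approx = TRUE)
    nmax <- max(pool$members)
    ai_max <- addition_chain_min(nmax, exact_limit = config$chain_limit,
                                 allow_approx = TRUE)
    data.frame(run = r, seed = run_seed, mode = config$mode,
               steps = config$steps, pool_size = length(pool$members),
               max_length = nmax,
               exploration_ratio = exploration_ratio(dag),
               max_assembly_index = ai_max$index,
               max_assembly_index_log2 = log2(nmax),
               ai_approximate = ai_max$approximate)
  })
  per_run <- do.call(rbind, rows)
  stat_cols <- c("pool_size", "max_length", "exploration_ratio",
                 "max_assembly_index", "max_assembly_index_log2")
  summary <- data.frame(
    statistic = stat_cols,
    mean = vapply(stat_cols, function(cn) mean(per_run[[cn]]), numeric(1)),
    sd = vapply(stat_cols, function(cn) sd(per_run[[cn]]), numeric(1)),
    mode = config$mode, runs = config$runs, steps = config$steps,
    seed = config$seed, row.names = NULL)
  list(per_run = per_run, summary = summary, config = config)
}

#' Build a simulation configuration
#'
#' @param mode `"undirected"` or `"directed"`.
#' @param steps Assembly steps per run (>= 1).
#' @param runs Number of repeated runs (>= 1).
#' @param seed Integer random seed (recorded in all outputs).
#' @param chain_limit Exact addition-chain limit for joint-space pathways.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(mode = c("undirected", "directed"), steps = 1000L,
                       runs = 25L, seed = 1L, chain_limit = 1024L) {
  validate_config(list(mode = match.arg(mode), steps = steps, runs = runs,
                       seed = seed, chain_limit = chain_limit))
}

validate_config <- function(config) {
  stopifnot(is.list(config))
  if (is.null(config$chain_limit)) config$chain_limit <- 1024L
  if (!config$mode %in% c("undirected", "directed"))
    stop("mode must be 'undirected' or 'directed'")
  if (is.null(config$steps) || config$steps < 1) stop("steps must be >= 1")
  if (is.null(config$runs) || config$runs < 1) stop("runs must be >= 1")
  if (is.null(config$seed)) stop("a seed is required (it is recorded in all outputs)")
  config$steps <- as.integer(config$steps)
  config$runs <- as.integer(config$runs)
  config$seed <- as.integer(config$seed)
  structure(config, class = "sim_config")
}
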