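#' @useDynLib assemblyr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbinom runif setNames sd binom.test coef lm rexp
#' @importFrom utils head read.delim write.table packageVersion
NULL

#' Canonicalized discrete objects for assembly theory
#'
#' An assembly object is a finite, distinguishable, breakable object built
#' from elementary units by recursive joining. Three kinds are supported:
#' character strings (elementary units are single characters, joining is
#' concatenation), homopolymers (an integer chain length, joining is length
#' addition) and molecular graphs (elementary units are bonds; see
#' [as_molgraph()]).
#'
#' Canonical forms are identical for objects equal under the kind's notion of
#' equality: string equality, length equality, or labelled graph isomorphism.
#'
#' @param x A raw object: a single non-empty character string, a positive
#'   integer length, or a molecular graph (see [as_molgraph()]).
#' @param kind One of `"string"`, `"homopolymer"`, `"molgraph"`.
#' @return An object of class `assembly_object` with fields `kind`, `payload`
#'   (canonical form) and `size` (number of elementary units).
#' @examples
#' canonicalize("ABBA", "string")
#' canonicalize(8, "homopolymer")
#' @export
canonicalize <- function(x, kind = c("string", "homopolymer", "molgraph")) {
  if (inherits(x, "assembly_object")) return(x)  # idempotent
  kind <- match.arg(kind)
  switch(kind,
    string = {
      if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L)
        stop("empty or invalid string object: a string must be a single non-empty character value")
      structure(list(kind = "string", payload = x, size = nchar(x)),
                class = c("assembly_string", "assembly_object"))
    },
    homopolymer = {
      n <- suppressWarnings(as.numeric(x))
      if (length(n) != 1L || is.na(n) || n < 1 || n != floor(n))
        stop("empty or invalid homopolymer object: length must be a positive integer")
      structure(list(kind = "homopolymer", payload = n, size = n),
                class = c("assembly_homopolymer", "assembly_object"))
    },
    molgraph = as_molgraph(x)
  )
}

#' @export
print.assembly_object <- function(x, ...) {
  cat(sprintf("<assembly %s> size %s\n", x$kind, format(x$size)), sep = "")
  if (x$kind == "string") cat("  ", x$payload, "\n", sep = "")
  invisible(x)
}

#' Join two assembly objects
#'
#' The elementary operation of assembly theory: two objects available in an
#' assembly pool combine to form a new object. Strings concatenate (ordered,
#' non-commutative); homopolymer lengths add; molecular graphs form an
#' edge-disjoint union fusing a declared set of shared atoms (see
#' [join_molgraph()]).
#'
#' @param x,y Assembly objects of the same kind.
#' @param ... Passed to kind-specific methods (e.g. `fuse` for molecular
#'   graphs).
#' @return The joined `assembly_object`.
#' @examples
#' join(canonicalize("AB", "string"), canonicalize("RA", "string"))
#' @export
join <- function(x, y, ...) {
  x <- as_assembly_object(x)
  y <- as_assembly_object(y)
  if (x$kind != y$kind)
    stop(sprintf("cannot join objects of different kinds: %s and %s", x$kind, y$kind))
  UseMethod("join")
}

#' @export
join.assembly_string <- function(x, y, ...)
  canonicalize(paste0(x$payload, y$payload), "string")

#' @export
join.assembly_homopolymer <- function(x, y, ...)
  canonicalize(x$payload + y$payload, "homopolymer")

#' @export
join.assembly_molgraph <- function(x, y, ...) join_molgraph(x, y, ...)

# Coerce bare strings / numbers when the intent is unambiguous.
as_assembly_object <- function(x) {
  if (inherits(x, "assembly_object")) return(x)
  if (is.character(x)) return(canonicalize(x, "string"))
  if (is.numeric(x)) return(canonicalize(x, "homopolymer"))
  stop("not an assembly object")
}

#' Lower and upper bounds on the assembly index
#'
#' The assembly index of an object of size `n` (elementary-unit count) lies in
#' `[ceiling(log2(n)), n - 1]`: each join at best doubles the size, and
#' building unit-by-unit always succeeds in `n - 1` steps.
#'
#' @param obj An `assembly_object` (any kind).
#' @return Named integer vector with elements `lower` and `upper`.
#' @examples
#' assembly_index_bounds(canonicalize(8, "homopolymer"))
#' @export
assembly_index_bounds <- function(obj) {
  obj <- as_assembly_object(obj)
  n <- obj$size
  c(lower = as.integer(ceiling(log2(n))), upper = as.integer(max(n - 1, 0)))
}

#' Assembly index and shortest pathway of an object
#'
#' Generic front-end dispatching on object kind: exact search for strings
#' ([assembly_index_string()]), minimal addition chains for homopolymers
#' ([addition_chain_min()]) and branch-and-bound for molecular graphs
#' ([molecular_assembly_index()]).
#'
#' @param obj An `assembly_object`, or a bare string / integer length.
#' @param ... Passed to the kind-specific search.
#' @return A list with elements `index` (integer) and `pathway`
#'   (an `assembly_pathway`), plus kind-specific extras.
#' @export
assembly_index <- function(obj, ...) {
  obj <- as_assembly_object(obj)
  switch(obj$kind,
    string = assembly_index_string(obj, ...),
    homopolymer = {
      res <- addition_chain_min(obj$payload, ...)
      res$pathway <- chain_to_pathway(res$chain)
      res
    },
    molgraph = molecular_assembly_index(obj, ...)
  )
}

# ---- Assembly pathways -----------------------------------------------------

new_pathway <- function(target, steps) {
  structure(list(target = target, steps = steps, length = length(steps)),
            class = "assembly_pathway")
}

#' @export
print.assembly_pathway <- function(x, ...) {
  cat(sprintf("<assembly pathway> %d step(s) to a %s of size %s\n",
              x$length, x$target$kind, format(x$target$size)))
  for (s in x$steps)
    cat("  ", format_operand(s$left), " + ", format_operand(s$right),
        " -> ", format_operand(s$product), "\n", sep = "")
  invisible(x)
}

format_operand <- function(o) {
  if (o$kind == "string") o$payload
  else if (o$kind == "homopolymer") format(o$payload)
  else sprintf("[%d-bond fragment]", o$size)
}

#' Serialize a pathway as `x+y=z;...`
#' @param p An `assembly_pathway`.
#' @return A single character string.
#' @export
format_pathway <- function(p) {
  paste(vapply(p$steps, function(s)
    paste0(format_operand(s$left), "+", format_operand(s$right), "=",
           format_operand(s$product)), character(1)), collapse = ";")
}

#' Replay an assembly pathway
#'
#' Executes a pathway's steps from the elementary units, checking the
#' assembly-pool recursion: every operand must be elementary or the product of
#' a strictly earlier step, and each product must equal the join of its
#' operands (for molecular graphs, sizes must add and the final product must
#' match the target's canonical form). Returns the rebuilt target.
#'
#' @param p An `assembly_pathway`.
#' @return The target `assembly_object`, rebuilt; errors if the pathway is
#'   invalid.
#' @export
replay_pathway <- function(p) {
  stopifnot(inherits(p, "assembly_pathway"))
  kind <- p$target$kind
  key <- function(o) {
    if (kind == "molgraph") molgraph_certificate(o) else as.character(o$payload)
  }
  pool <- new.env(parent = emptyenv())
  is_available <- function(o) {
    if (o$size == 1L || o$size == 1) return(TRUE)  # elementary unit
    !is.null(pool[[key(o)]])
  }
  last <- NULL
  for (s in p$steps) {
    if (!is_available(s$left)) stop("pathway invalid: left operand not available")
    if (!is_available(s$right)) stop("pathway invalid: right operand not available")
    if (kind %in% c("string", "homopolymer")) {
      prod <- join(s$left, s$right)
      if (!identical(key(prod), key(s$product)))
        stop("pathway invalid: product does not equal join of operands")
    } else {
      if (s$left$size + s$right$size != s$product$size)
        stop("pathway invalid: product size must be the sum of operand sizes")
      prod <- s$product
    }
    pool[[key(prod)]] <- TRUE
    last <- prod
  }
  if (!identical(key(last), key(p$target)))
    stop("pathway invalid: final product does not equal the target")
  p$target
}

chain_to_pathway <- function(chain) {
  # chain: data.frame with value, i, j (summands); rows after the initial 1
  steps <- lapply(seq_len(nrow(chain)), function(r) {
    list(left = canonicalize(chain$i[r], "homopolymer"),
         right = canonicalize(chain$j[r], "homopolymer"),
         product = canonicalize(chain$value[r], "homopolymer"))
  })
  tgt <- if (nrow(chain)) canonicalize(chain$value[nrow(chain)], "homopolymer")
         else canonicalize(1, "homopolymer")
  new_pathway(tgt, steps)
}
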