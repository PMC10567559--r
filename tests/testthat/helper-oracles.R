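# Independent brute-force oracles. These deliberately use different
# algorithm families from the package's search code: bottom-up enumeration
# over assembly-pool states (strings, addition chains) and a bottom-up
# minimal-construction-set search over the connected-subgraph universe
# (molecules). They are only feasible for tiny inputs.

# ---- strings: bottom-up pool-state search ----------------------------------

string_oracle_index <- function(s) {
  n <- nchar(s)
  if (n == 1L) return(0L)
  subs <- unique(unlist(lapply(seq_len(n), function(i)
    vapply(i:n, function(j) substr(s, i, j), character(1)))))
  is_sub <- function(x) x %in% subs
  memo <- new.env(parent = emptyenv())
  exists_pathway <- function(pool, d) {
    if (s %in% pool) return(TRUE)
    if (d == 0L) return(FALSE)
    key <- paste(d, paste(sort(pool), collapse = "\r"))
    if (!is.null(memo[[key]])) return(FALSE)
    maxlen <- max(nchar(pool))
    if (maxlen * 2^d < n) { memo[[key]] <- TRUE; return(FALSE) }
    for (u in pool) for (v in pool) {
      w <- paste0(u, v)
      if (nchar(w) <= n && is_sub(w) && !(w %in% pool)) {
        if (exists_pathway(c(pool, w), d - 1L)) return(TRUE)
      }
    }
    memo[[key]] <- TRUE
    FALSE
  }
  chars <- unique(strsplit(s, "")[[1]])
  d <- 0L
  while (!exists_pathway(chars, d)) d <- d + 1L
  d
}

# ---- addition chains: naive DFS over increasing chains ---------------------

chain_oracle_index <- function(n) {
  if (n == 1) return(0L)
  best <- Inf
  rec <- function(chain, depth) {
    top <- chain[length(chain)]
    if (top == n) { best <<- min(best, depth); return(invisible(NULL)) }
    if (depth >= best) return(invisible(NULL))
    if (top * 2^(best - depth - 1) < n) return(invisible(NULL))
    sums <- unique(as.vector(outer(chain, chain, `+`)))
    for (s in sort(sums[sums > top & sums <= n], decreasing = TRUE))
      rec(c(chain, s), depth + 1L)
  }
  rec(1, 0L)
  as.integer(best)
}

# ---- molecules: bottom-up minimal-construction-set search ------------------

# Exhaustive: universe = isomorphism classes of connected edge subsets of the
# target; a class is buildable from a split into two connected, edge-disjoint
# parts; the assembly index is the size of the smallest construction set
# (classes with >= 2 bonds) closed under splits and containing the target.
mol_oracle_index <- function(g) {
  g <- assemblyr::as_molgraph(g)
  E <- g$size
  if (E == 1L) return(0L)
  b <- g$payload$bonds
  edge_atoms <- cbind(b$i, b$j)
  adj <- lapply(seq_len(E), function(e)
    setdiff(which(b$i %in% edge_atoms[e, ] | b$j %in% edge_atoms[e, ]), e))
  subs <- assemblyr:::enumerate_connected_edge_subsets(adj, E, E)
  certs <- vapply(subs$masks, function(m) assemblyr::molgraph_certificate(
    assemblyr:::molgraph_fragment(g, assemblyr:::mask_to_edges(m))), character(1))
  classes <- unique(certs)
  class_size <- vapply(classes, function(cl) subs$sizes[match(cl, certs)], integer(1))
  # split options per class, from one representative mask per class
  edge_set_connected <- function(mask) {
    es <- assemblyr:::mask_to_edges(mask)
    vs <- unique(as.vector(edge_atoms[es, , drop = FALSE]))
    sub_edges <- edge_atoms[es, , drop = FALSE]
    remap <- match(sub_edges, vs)
    dim(remap) <- dim(sub_edges)
    assemblyr:::edges_connected(remap, length(vs))
  }
  splits <- lapply(classes, function(cl) {
    S <- subs$masks[match(cl, certs)]
    k <- subs$sizes[match(cl, certs)]
    if (k < 2L) return(list())
    parts <- which(bitwAnd(subs$masks, S) == subs$masks & subs$masks != S)
    out <- list()
    seen <- character(0)
    for (p in parts) {
      Amask <- subs$masks[p]
      Bmask <- bitwAnd(S, bitwNot(Amask))
      if (Bmask == 0L || !edge_set_connected(Bmask)) next
      cb <- assemblyr::molgraph_certificate(
        assemblyr:::molgraph_fragment(g, assemblyr:::mask_to_edges(Bmask)))
      pair <- sort(c(certs[p], cb))
      pk <- paste(pair, collapse = "\r")
      if (pk %in% seen) next
      seen <- c(seen, pk)
      out[[length(out) + 1L]] <- pair
    }
    out
  })
  names(splits) <- classes
  target <- certs[match(mask_all_local(E), subs$masks)]
  elementary <- classes[class_size == 1L]
  dfs <- function(goals, chosen, budget) {
    if (length(goals) == 0L) return(TRUE)
    if (length(goals) > budget) return(FALSE)
    sizes <- class_size[match(goals, classes)]
    gcl <- goals[order(-sizes)][1L]
    if (ceiling(log2(max(sizes))) > budget) return(FALSE)
    rest <- setdiff(goals, gcl)
    chosen2 <- c(chosen, gcl)
    for (sp in splits[[gcl]]) {
      ng <- unique(c(rest, setdiff(sp, c(elementary, chosen2))))
      if (dfs(ng, chosen2, budget - 1L)) return(TRUE)
    }
    FALSE
  }
  d <- ceiling(log2(E))
  while (!dfs(target, character(0), d)) d <- d + 1L
  as.integer(d)
}

mask_all_local <- function(E) {
  m <- 0L
  for (e in seq_len(E)) m <- bitwOr(m, bitwShiftL(1L, e - 1L))
  m
}

# ---- small-graph enumeration -----------------------------------------------

# all connected graphs with exactly `n_edges` edges as edge lists over
# unlabelled vertices, grown by edge addition, deduplicated by certificate
# with uniform labels
connected_edge_shapes <- function(n_edges) {
  shapes <- list(matrix(c(1L, 2L), ncol = 2))
  for (k in seq_len(n_edges - 1L)) {
    nxt <- list()
    seen <- character(0)
    for (sh in shapes) {
      nv <- max(sh)
      cand <- rbind(
        do.call(rbind, lapply(seq_len(nv), function(v) c(v, nv + 1L))),
        t(combn(nv, 2L))
      )
      for (r in seq_len(nrow(cand))) {
        u <- cand[r, 1]; v <- cand[r, 2]
        dup <- any(sh[, 1] == pmin(u, v) & sh[, 2] == pmax(u, v))
        if (dup) next
        sh2 <- rbind(sh, c(pmin(u, v), pmax(u, v)))
        g2 <- assemblyr::as_molgraph(list(atoms = rep("C", max(sh2)),
                                          bonds = data.frame(i = sh2[, 1], j = sh2[, 2],
                                                             order = 1L)))
        cert <- assemblyr::molgraph_certificate(g2)
        if (cert %in% seen) next
        seen <- c(seen, cert)
        nxt[[length(nxt) + 1L]] <- sh2
      }
    }
    shapes <- nxt
  }
  shapes
}

# all distinct labelled graphs for a shape: element and bond-order
# assignments, deduplicated by certificate; optionally capped via seeded
# sampling of the raw assignment space
labelled_graphs_for_shape <- function(shape, elements = c("C", "O", "N"),
                                      orders = c(1L, 2L), sample_n = Inf,
                                      seed = NULL) {
  nv <- max(shape); ne <- nrow(shape)
  el_grid <- do.call(expand.grid, c(rep(list(elements), nv),
                                    stringsAsFactors = FALSE))
  or_grid <- do.call(expand.grid, rep(list(orders), ne))
  total <- nrow(el_grid) * nrow(or_grid)
  take <- if (is.finite(sample_n) && sample_n < total) {
    if (!is.null(seed)) set.seed(seed)
    sample.int(total, sample_n)
  } else seq_len(total)
  out <- list()
  seen <- character(0)
  for (t in take) {
    ei <- (t - 1L) %% nrow(el_grid) + 1L
    oi <- (t - 1L) %/% nrow(el_grid) + 1L
    g <- assemblyr::as_molgraph(list(
      atoms = unlist(el_grid[ei, ], use.names = FALSE),
      bonds = data.frame(i = shape[, 1], j = shape[, 2],
                         order = unlist(or_grid[oi, ], use.names = FALSE))))
    cert <- assemblyr::molgraph_certificate(g)
    if (cert %in% seen) next
    seen <- c(seen, cert)
    out[[length(out) + 1L]] <- g
  }
  out
}
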