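# Bond-based molecular assembly index by top-down branch-and-bound.
#
# Duality used by the search: an assembly pathway that constructs a molecule
# with E bonds in E - 1 - s steps exists exactly when s "duplication savings"
# can be collected by repeatedly matching two edge-disjoint isomorphic
# connected subgraphs (k bonds each, k >= 2) in the remaining graph and
# deleting one copy's edges, each match saving k - 1 steps (the deleted copy
# is obtained by reusing the other copy, which the pathway builds once).
# Not every match sequence corresponds to a realizable pathway: matches must
# nest laminarly inside the first-built ("representative") copy of each
# reused structure, because a structure is built exactly once and later uses
# are opaque copies. Unrestricted removal sequences can straddle region
# boundaries and overcount savings (diethyl phthalate is a counterexample:
# unrestricted matching claims one saving too many). The authoritative
# search is therefore laminar-restricted and target-directed: an unrestricted
# memoized search provides a cheap upper bound on savings, and the laminar
# search certifies the largest attainable target with an explicit witness,
# which unfolds into a replayable pathway (verified at run time).

#' Exact molecular assembly index
#'
#' Minimal number of join steps needed to build a molecular graph from its
#' bonds, where each step joins two structures available on the pathway
#' (elementary bonds plus earlier products) and any structure, once formed,
#' may be reused at no extra cost.
#'
#' @param mol A molgraph object (see [as_molgraph()], [parse_molecule()]).
#' @param exact_limit Largest bond count searched exactly (default 30);
#'   larger molecules are refused, reporting [assembly_index_bounds()].
#' @param allow_ring_closure Permit joins that fuse both endpoints of an
#'   elementary bond onto an existing structure (closing a ring). With
#'   `FALSE`, cyclic molecules cannot be assembled and are rejected.
#' @return List with `index`, `pathway` (replayable; see [replay_pathway()])
#'   and `savings` (steps saved by substructure reuse relative to the
#'   bond-count upper bound).
#' @export
molecular_assembly_index <- function(mol, exact_limit = 30L, allow_ring_closure = TRUE) {
  g <- as_molgraph(mol)
  E <- g$size
  if (E > exact_limit) {
    b <- assembly_index_bounds(g)
    stop(sprintf("molecule with %d bonds exceeds the exact-search limit %d; bounds are [%d, %d]",
                 E, exact_limit, b["lower"], b["upper"]))
  }
  n_atoms <- length(g$payload$atoms)
  cyclic <- E > n_atoms - 1L
  if (!allow_ring_closure && cyclic)
    stop("molecule contains rings, which cannot be assembled without ring-closing joins")
  if (E == 1L)
    return(list(index = 0L, pathway = new_pathway(g, list()), savings = 0L))

  ctx <- mol_search_context(g)
  s_upper <- mol_max_savings(ctx)
  witness <- NULL
  s_max <- 0L
  for (tgt in seq(s_upper, 0L)) {
    witness <- mol_find_witness(ctx, tgt)
    if (!is.null(witness)) { s_max <- tgt; break }
  }
  index <- E - 1L - s_max
  pathway <- mol_build_pathway(ctx, witness)
  stopifnot(pathway$length == index)  # the witness must certify the index
  list(index = as.integer(index), pathway = pathway, savings = as.integer(s_max))
}

# ---- search context: subgraph classes and duplicate pairs ------------------

mol_search_context <- function(g) {
  b <- g$payload$bonds
  E <- nrow(b)
  edge_atoms <- cbind(b$i, b$j)
  # edges adjacent to each edge (sharing an atom)
  adj <- lapply(seq_len(E), function(e) {
    setdiff(which(b$i %in% edge_atoms[e, ] | b$j %in% edge_atoms[e, ]), e)
  })
  kmax <- E %/% 2L
  subs <- enumerate_connected_edge_subsets(adj, E, kmax)
  certs <- vapply(subs$masks, function(m)
    molgraph_certificate(molgraph_fragment(g, mask_to_edges(m))), character(1))
  # duplicate pairs: same certificate, edge-disjoint, >= 2 bonds
  pairA <- integer(0); pairB <- integer(0); pairK <- integer(0); pairC <- character(0)
  for (cl in unique(certs[subs$sizes >= 2L])) {
    idx <- which(certs == cl & subs$sizes >= 2L)
    if (length(idx) < 2L) next
    for (a in idx) for (bb in idx) {
      if (a != bb && bitwAnd(subs$masks[a], subs$masks[bb]) == 0L) {
        pairA <- c(pairA, subs$masks[a]); pairB <- c(pairB, subs$masks[bb])
        pairK <- c(pairK, subs$sizes[a]); pairC <- c(pairC, cl)
      }
    }
  }
  ord <- order(-pairK, pairA, pairB)
  list(g = g, E = E, edge_atoms = edge_atoms,
       full_mask = mask_all(E),
       pairA = pairA[ord], pairB = pairB[ord],
       pairK = pairK[ord], pairC = pairC[ord])
}

mask_all <- function(E) {
  m <- 0L
  for (e in seq_len(E)) m <- bitwOr(m, bitwShiftL(1L, e - 1L))
  m
}
mask_to_edges <- function(mask) which(bitwAnd(mask, bitwShiftL(1L, 0:29)) != 0L)
popcount <- function(mask) sum(bitwAnd(mask, bitwShiftL(1L, 0:29)) != 0L)

# all connected edge-induced subgraphs with <= kmax edges, as bitmasks;
# enumerated by growth from each minimal edge with larger-indexed extensions
enumerate_connected_edge_subsets <- function(adj, E, kmax) {
  seen <- new.env(parent = emptyenv())
  masks <- integer(0); sizes <- integer(0)
  for (e in seq_len(E)) {
    start <- bitwShiftL(1L, e - 1L)
    frontier <- list(list(mask = start, ext = adj[[e]][adj[[e]] > e], k = 1L))
    masks <- c(masks, start); sizes <- c(sizes, 1L)
    while (length(frontier)) {
      nxt <- list()
      for (node in frontier) {
        if (node$k >= kmax) next
        for (f in node$ext) {
          m2 <- bitwOr(node$mask, bitwShiftL(1L, f - 1L))
          key <- as.character(m2)
          if (!is.null(seen[[key]])) next
          seen[[key]] <- TRUE
          ext2 <- unique(c(node$ext, adj[[f]][adj[[f]] > e]))
          ext2 <- ext2[bitwAnd(m2, bitwShiftL(1L, ext2 - 1L)) == 0L]
          nxt[[length(nxt) + 1L]] <- list(mask = m2, ext = ext2, k = node$k + 1L)
          masks <- c(masks, m2); sizes <- c(sizes, node$k + 1L)
        }
      }
      frontier <- nxt
    }
  }
  list(masks = masks, sizes = sizes)
}

# admissible cap on further savings from F remaining edges: each match keeps
# one copy, so edges at best halve per match, giving <= F - 1 - ceil(log2 F)
savings_cap <- function(F) {
  if (F < 4L) return(0L)
  as.integer(F - 1L - ceiling(log2(F)))
}

# ---- value search: maximal savings, memoized on the remaining-edge mask ----

mol_max_savings <- function(ctx) {
  memo <- new.env(parent = emptyenv())
  pa <- ctx$pairA; pb <- ctx$pairB; pk <- ctx$pairK
  rec <- function(mask, cand, F) {
    key <- as.character(mask)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    ok <- cand[bitwAnd(pa[cand], mask) == pa[cand] & bitwAnd(pb[cand], mask) == pb[cand]]
    best <- 0L
    cap <- savings_cap(F)
    for (p in ok) {
      k <- pk[p]
      if (best >= cap) break
      if (k - 1L + savings_cap(F - k) <= best) next  # cannot improve
      s <- k - 1L + rec(bitwAnd(mask, bitwNot(pb[p])), ok, F - k)
      if (s > best) best <- s
    }
    memo[[key]] <- best
    best
  }
  rec(ctx$full_mask, seq_along(pa), ctx$E)
}

# ---- witness search and pathway reconstruction -----------------------------

# Laminar-restricted witness: a sequence of matches attaining the target
# savings in which every region nests properly inside representative (first
# built) copies, so it unfolds into an explicit pathway. Non-increasing match
# sizes with index tie-breaking keep the search deterministic.
mol_find_witness <- function(ctx, target) {
  if (target == 0L) return(list())
  pa <- ctx$pairA; pb <- ctx$pairB; pk <- ctx$pairK; pc <- ctx$pairC
  found <- NULL
  regions_ok <- function(X, is_B, regions, rep_of) {
    for (r in regions) {
      ov <- bitwAnd(X, r$mask)
      if (ov == 0L) next
      if (ov == X && ov == r$mask) {        # same region: reusing a kept copy
        if (is_B) return(FALSE)             # but a build may not be removed
      } else if (ov == X) {                 # X strictly inside r
        if (!r$rep) return(FALSE)
      } else if (ov == r$mask) {            # r strictly inside X
        if (is_B) return(FALSE)             # removal may not swallow a build
      } else return(FALSE)                  # straddling regions
    }
    TRUE
  }
  rec <- function(mask, F, sav, from, regions, reps) {
    if (sav == target) { found <<- regions; return(TRUE) }
    if (sav + savings_cap(F) < target) return(FALSE)
    for (p in seq(from, length(pa))) {
      A <- pa[p]; B <- pb[p]; k <- pk[p]; cl <- pc[p]
      if (sav + k - 1L > target) next
      if (bitwAnd(A, mask) != A || bitwAnd(B, mask) != B) next
      is_rep <- is.null(reps[[cl]])
      if (!regions_ok(A, FALSE, regions, reps)) next
      if (!regions_ok(B, TRUE, regions, reps)) next
      reps2 <- reps
      if (is_rep) reps2[[cl]] <- A
      regions2 <- regions
      # a non-representative A is a reused copy: kept, but nothing may nest
      # inside it later (rep = FALSE blocks that in regions_ok)
      if (!any(vapply(regions, function(r) r$mask == A, logical(1))))
        regions2[[length(regions2) + 1L]] <- list(mask = A, class = cl, rep = is_rep)
      regions2[[length(regions2) + 1L]] <- list(mask = B, class = cl, rep = FALSE)
      if (rec(bitwAnd(mask, bitwNot(B)), F - k, sav + k - 1L, p, regions2, reps2))
        return(TRUE)
    }
    FALSE
  }
  if (!rec(ctx$full_mask, ctx$E, 0L, 1L, list(), list())) return(NULL)
  found
}

mol_build_pathway <- function(ctx, regions) {
  g <- ctx$g
  # builds: one per class representative region, plus the whole molecule
  builds <- Filter(function(r) r$rep, regions)
  builds <- builds[order(vapply(builds, function(r) popcount(r$mask), integer(1)))]
  builds[[length(builds) + 1L]] <- list(mask = ctx$full_mask, class = "TARGET", rep = TRUE)
  steps <- list()
  for (bld in builds) {
    M <- bld$mask
    inside <- Filter(function(r) r$mask != M &&
                       bitwAnd(r$mask, M) == r$mask, regions)
    # maximal regions inside M become units; everything else is loose edges
    unit_masks <- integer(0)
    for (r in inside) {
      nested <- any(vapply(inside, function(q)
        q$mask != r$mask && bitwAnd(r$mask, q$mask) == r$mask, logical(1)))
      if (!nested) unit_masks <- c(unit_masks, r$mask)
    }
    unit_masks <- unique(unit_masks)
    loose <- setdiff(mask_to_edges(M), mask_to_edges(Reduce(bitwOr, c(0L, unit_masks))))
    pieces <- c(lapply(unit_masks, identity), as.list(bitwShiftL(1L, loose - 1L)))
    pieces <- pieces[order(vapply(pieces, function(m) min(mask_to_edges(m)), integer(1)))]
    cur <- pieces[[1L]]
    atoms_of <- function(m) unique(as.vector(ctx$edge_atoms[mask_to_edges(m), , drop = FALSE]))
    remaining <- pieces[-1L]
    while (length(remaining)) {
      cur_atoms <- atoms_of(cur)
      touch <- vapply(remaining, function(m) any(atoms_of(m) %in% cur_atoms), logical(1))
      pick <- which(touch)[1L]
      um <- remaining[[pick]]
      remaining <- remaining[-pick]
      prod_mask <- bitwOr(cur, um)
      steps[[length(steps) + 1L]] <- list(
        left = molgraph_fragment(g, mask_to_edges(cur)),
        right = molgraph_fragment(g, mask_to_edges(um)),
        product = molgraph_fragment(g, mask_to_edges(prod_mask)))
      cur <- prod_mask
    }
  }
  new_pathway(g, steps)
}
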