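# Molecular graphs for bond-based assembly: heavy atoms as vertices, bonds as
# elementary units. Bond orders are coded 1, 2, 3, and 4 for aromatic (a
# single uniform label, so any Kekule structure of an aromatic ring maps to
# the same graph). Equality is labelled graph isomorphism, decided through a
# canonical certificate computed by colour refinement with individualization
# (minimum certificate over all branchings, so isomorphic graphs always agree).

BOND_LABELS <- c("1" = 1L, "2" = 2L, "3" = 3L, "ar" = 4L)

#' Construct a molecular graph object
#'
#' @param x A list with `atoms` (character vector of element symbols) and
#'   `bonds` (data frame with integer columns `i`, `j` and `order`, orders
#'   coded 1/2/3 and 4 for aromatic), or an existing molgraph.
#' @return An `assembly_object` of kind `molgraph`; `size` is the bond count.
#' @export
as_molgraph <- function(x) {
  if (inherits(x, "assembly_molgraph")) return(x)
  if (!is.list(x) || is.null(x$atoms) || is.null(x$bonds))
    stop("empty or invalid molgraph object: need atoms and bonds")
  atoms <- as.character(x$atoms)
  b <- as.data.frame(x$bonds)
  if (nrow(b) < 1L) stop("empty or invalid molgraph object: at least one bond required")
  b$i <- as.integer(b$i); b$j <- as.integer(b$j); b$order <- as.integer(b$order)
  if (any(b$i < 1L | b$i > length(atoms) | b$j < 1L | b$j > length(atoms) | b$i == b$j))
    stop("invalid molgraph: bond endpoints out of range")
  if (!all(b$order %in% BOND_LABELS)) stop("invalid molgraph: unknown bond order code")
  key <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
  if (anyDuplicated(key)) stop("invalid molgraph: duplicate bonds")
  if (!edges_connected(cbind(b$i, b$j), length(atoms)))
    stop("invalid molgraph: graph must be connected")
  structure(list(kind = "molgraph",
                 payload = list(atoms = atoms, bonds = b[c("i", "j", "order")]),
                 size = nrow(b)),
            class = c("assembly_molgraph", "assembly_object"))
}

# connectivity over all n vertices via the given edges (2-col matrix)
edges_connected <- function(e, n) {
  if (n == 1L) return(TRUE)
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  for (r in seq_len(nrow(e))) {
    ra <- find(e[r, 1]); rb <- find(e[r, 2])
    if (ra != rb) parent[ra] <- rb
  }
  length(unique(vapply(seq_len(n), find, integer(1)))) == 1L
}

#' Join two molecular graphs by fusing shared atoms
#'
#' The molecular join contract: the product is the union of the two operand
#' graphs with a declared set of shared atoms fused; every bond of the
#' product comes from exactly one operand (no new bonds appear, and fusing
#' must not make two bonds coincide). A ring-closing join is the special case
#' of joining with an elementary bond while fusing both of its endpoints.
#'
#' @param x,y Molgraph objects.
#' @param fuse Two-column matrix of atom index pairs (column 1: atom in `x`,
#'   column 2: atom in `y`) to be fused; elements must match. May have zero
#'   rows only if the result is still connected (it never is), so at least
#'   one fused atom is required.
#' @return The joined molgraph; its bond count is the sum of the operands'.
#' @export
join_molgraph <- function(x, y, fuse) {
  x <- as_molgraph(x); y <- as_molgraph(y)
  fuse <- matrix(as.integer(fuse), ncol = 2)
  ax <- x$payload$atoms; ay <- y$payload$atoms
  if (nrow(fuse) == 0L) stop("molgraph join requires at least one fused atom (product must be connected)")
  if (any(ax[fuse[, 1]] != ay[fuse[, 2]]))
    stop("cannot fuse atoms with different elements")
  if (anyDuplicated(fuse[, 1]) || anyDuplicated(fuse[, 2]))
    stop("fusion map must be injective")
  map_y <- rep(NA_integer_, length(ay))
  map_y[fuse[, 2]] <- fuse[, 1]
  new_idx <- which(is.na(map_y))
  map_y[new_idx] <- length(ax) + seq_along(new_idx)
  atoms <- c(ax, ay[new_idx])
  by <- y$payload$bonds
  bonds <- rbind(x$payload$bonds,
                 data.frame(i = map_y[by$i], j = map_y[by$j], order = by$order))
  as_molgraph(list(atoms = atoms, bonds = bonds))  # validates bond disjointness
}

# ---- canonical certificate -------------------------------------------------

# Colour refinement on (element, incident bond multiset) with
# individualization; certificate = lexicographically smallest adjacency
# encoding over all discrete colourings explored. Cached on the object when
# possible.

#' Canonical certificate of a molecular graph
#'
#' Isomorphism-invariant string: two molgraphs have equal certificates if and
#' only if they are isomorphic as element- and bond-order-labelled graphs.
#'
#' @param g A molgraph object.
#' @return A character scalar.
#' @export
molgraph_certificate <- function(g) {
  g <- as_molgraph(g)
  cert_atoms_bonds(g$payload$atoms, g$payload$bonds)
}

cert_atoms_bonds <- function(atoms, bonds) {
  n <- length(atoms)
  m <- nrow(bonds)
  ei <- bonds$i; ej <- bonds$j; eo <- bonds$order
  # adjacency lists
  nb <- vector("list", n); no <- vector("list", n)
  for (r in seq_len(m)) {
    nb[[ei[r]]] <- c(nb[[ei[r]]], ej[r]); no[[ei[r]]] <- c(no[[ei[r]]], eo[r])
    nb[[ej[r]]] <- c(nb[[ej[r]]], ei[r]); no[[ej[r]]] <- c(no[[ej[r]]], eo[r])
  }
  refine <- function(col) {
    repeat {
      sig <- vapply(seq_len(n), function(v) {
        s <- sort(paste0(no[[v]], ":", col[nb[[v]]]))
        paste0(col[v], "|", paste(s, collapse = ","))
      }, character(1))
      new_col <- match(sig, sort(unique(sig)))
      # signatures embed the old colour, so cells only ever split; the
      # partition is stable as soon as the class count stops growing
      if (max(new_col) == max(col)) return(new_col)
      col <- new_col
    }
  }
  encode <- function(ord) {
    # ord: vertex order (rank position r holds vertex ord[r])
    rk <- integer(n); rk[ord] <- seq_len(n)
    a <- pmin(rk[ei], rk[ej]); b <- pmax(rk[ei], rk[ej])
    es <- sprintf("%02d-%02d-%d", a, b, eo)
    paste(paste(atoms[ord], collapse = ","), paste(sort(es), collapse = ";"), sep = "#")
  }
  best <- NULL
  search <- function(col) {
    col <- refine(col)
    tab <- table(col)
    if (all(tab == 1L)) {
      s <- encode(order(col))
      if (is.null(best) || s < best) best <<- s
      return(invisible(NULL))
    }
    cell <- as.integer(names(tab)[tab > 1L][1L])  # first non-singleton colour
    for (v in which(col == cell)) {
      col2 <- col
      col2[v] <- 0L  # individualize: strictly smallest colour
      col2 <- match(col2, sort(unique(col2)))
      search(col2)
    }
  }
  search(match(atoms, sort(unique(atoms))))
  best
}

# ---- parsing ---------------------------------------------------------------

#' Parse a molecule into a heavy-atom molecular graph
#'
#' Accepts a SMILES string, the text of a V2000 molfile/SDF record, or a path
#' to an SDF file (first record). Hydrogens are suppressed; aromatic rings
#' (perceived via ChemmineR) get the uniform aromatic bond label.
#'
#' @param input SMILES string, molfile text, or file path.
#' @param format `"auto"` (default), `"smiles"` or `"sdf"`.
#' @return A molgraph `assembly_object`.
#' @examples
#' \dontrun{parse_molecule("CC")}
#' @export
parse_molecule <- function(input, format = c("auto", "smiles", "sdf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (file.exists(input) || grepl("V2000", input)) "sdf" else "smiles"
  }
  if (format == "smiles") {
    if (!requireNamespace("ChemmineOB", quietly = TRUE))
      stop("SMILES parsing requires ChemmineOB")
    sdf_text <- tryCatch(ChemmineOB::convertFormat("SMI", "SDF", source = input),
                         error = function(e) "")
    if (!nzchar(sdf_text) || !grepl("V2000", sdf_text))
      stop(sprintf("could not parse molecule input '%s'", input))
    mols <- read_molecules_text(sdf_text)
  } else {
    txt <- if (file.exists(input)) paste(readLines(input, warn = FALSE), collapse = "\n") else input
    if (!grepl("V2000", txt)) stop(sprintf("could not parse molecule input '%s'", substr(input, 1, 60)))
    mols <- read_molecules_text(txt)
  }
  if (length(mols) == 0L) stop(sprintf("could not parse molecule input '%s'", substr(input, 1, 60)))
  mols[[1L]]
}

#' Read all molecules from an SDF file
#' @param path Path to an SDF/molfile.
#' @return Named list of molgraph objects (one per record).
#' @export
read_molecules <- function(path) {
  read_molecules_text(paste(readLines(path, warn = FALSE), collapse = "\n"))
}

read_molecules_text <- function(txt) {
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  if (!grepl("\\$\\$\\$\\$", txt)) txt <- paste0(txt, "\n$$$$\n")
  writeLines(txt, tf)
  sdfset <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(tf)),
                     error = function(e) NULL)
  if (is.null(sdfset)) return(list())
  out <- list()
  for (k in seq_along(sdfset)) {
    g <- tryCatch(sdf_to_molgraph(sdfset[[k]]), error = function(e) NULL)
    if (!is.null(g)) out[[length(out) + 1L]] <- g
  }
  names(out) <- ChemmineR::sdfid(sdfset)[seq_along(out)]
  out
}

sdf_to_molgraph <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                      order = as.integer(bb[, 3]))
  # uniform aromatic label from perceived aromatic rings (Kekule input)
  ar <- tryCatch(ChemmineR::rings(sdf, type = "all", arom = TRUE),
                 error = function(e) NULL)
  if (!is.null(ar) && length(ar$RINGS)) {
    for (r in seq_along(ar$RINGS)) {
      if (!isTRUE(ar$AROMATIC[[r]])) next
      idx <- as.integer(sub("^.*_", "", ar$RINGS[[r]]))
      ring_pairs <- cbind(idx, c(idx[-1L], idx[1L]))
      key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
      rkey <- paste(pmin(ring_pairs[, 1], ring_pairs[, 2]),
                    pmax(ring_pairs[, 1], ring_pairs[, 2]))
      bonds$order[key %in% rkey] <- BOND_LABELS[["ar"]]
    }
  }
  # suppress hydrogens
  heavy <- which(elements != "H")
  remap <- rep(NA_integer_, length(elements))
  remap[heavy] <- seq_along(heavy)
  keep <- bonds$i %in% heavy & bonds$j %in% heavy
  bonds <- bonds[keep, , drop = FALSE]
  bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
  as_molgraph(list(atoms = elements[heavy], bonds = bonds))
}

#' Molecular formula of a molgraph (heavy atoms only)
#' @param g A molgraph.
#' @return Character scalar such as `"C12O4"`.
#' @export
molgraph_formula <- function(g) {
  g <- as_molgraph(g)
  tab <- table(g$payload$atoms)
  paste0(names(tab), ifelse(tab > 1, tab, ""), collapse = "")
}

# fragment of g induced by an edge-index subset (atoms relabelled compactly)
molgraph_fragment <- function(g, edge_idx) {
  b <- g$payload$bonds[edge_idx, , drop = FALSE]
  vs <- sort(unique(c(b$i, b$j)))
  remap <- integer(max(vs)); remap[vs] <- seq_along(vs)
  as_molgraph(list(atoms = g$payload$atoms[vs],
                   bonds = data.frame(i = remap[b$i], j = remap[b$j], order = b$order)))
}
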