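# Seeded synthetic inputs for every object kind. These are first-class
# generators (not stored data): identical seeds give identical files, and
# each generator plants structure with a known constructive bound so
# downstream results can be sanity-checked.

#' Generate synthetic fixture files
#'
#' - `strings`: FASTA of strings of length `4 * (motif_len + pad_len)` built
#'   as four repeats of a block starting with a planted motif; the repeat
#'   construction bounds the assembly index by
#'   `(block_len - 1) + 2` (build one block, double twice), e.g. 5 for
#'   16-character strings with a 2-character motif.
#' - `homopolymers`: TSV of random lengths in `[1, max_len]`.
#' - `molecules`: SDF of random connected heavy-atom graphs with up to
#'   `max_bonds` bonds over C/N/O with single/double bonds (valence-capped).
#' - `ensembles`: TSV with controlled assembly-index and copy-number mixtures;
#'   `singletons = TRUE` forces all copy numbers to 1 (so A = 0 downstream).
#'
#' @param kind One of `"strings"`, `"homopolymers"`, `"molecules"`,
#'   `"ensembles"`.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed; identical seeds give identical fixtures.
#' @param n Number of records to generate.
#' @param motif,pad_len Planted motif and random padding per block (strings).
#' @param max_len Largest homopolymer length.
#' @param max_bonds Largest molecule size in bonds.
#' @param singletons All ensemble copy numbers 1 (ensembles).
#' @return Path of the file written, invisibly; a manifest is written
#'   alongside.
#' @export
make_fixtures <- function(kind = c("strings", "homopolymers", "molecules", "ensembles"),
                          dir = ".", seed = 1L, n = 10L, motif = "AB",
                          pad_len = 2L, max_len = 64L, max_bonds = 12L,
                          singletons = FALSE) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(seed))
  path <- file.path(dir, paste0("fixture_", kind,
                                switch(kind, strings = ".fasta",
                                       molecules = ".sdf", ".tsv")))
  if (kind == "strings") {
    seqs <- vapply(seq_len(n), function(i) {
      pad <- paste(sample(c("A", "B"), pad_len, replace = TRUE), collapse = "")
      strrep(paste0(motif, pad), 4L)
    }, character(1))
    writeLines(paste0(">planted", seq_len(n), "\n", seqs), path)
  } else if (kind == "homopolymers") {
    lens <- sample.int(max_len, n, replace = TRUE)
    write.table(data.frame(id = paste0("len", lens), length = lens), path,
                sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (kind == "molecules") {
    mols <- lapply(seq_len(n), function(i) random_molgraph(max_bonds))
    names(mols) <- paste0("rand", seq_len(n))
    write_molecules_sdf(mols, path)
  } else {
    a <- sample.int(6L, n, replace = TRUE) - 1L
    cn <- if (singletons) rep(1L, n) else sample.int(8L, n, replace = TRUE)
    write_ensemble_tsv(ensemble(paste0("obj", seq_len(n)), a, cn), path)
  }
  write_manifest(paste0(path, ".manifest.json"),
                 command = sprintf("make_fixtures('%s')", kind),
                 config = list(kind = kind, seed = seed, n = n, motif = motif,
                               pad_len = pad_len, max_len = max_len,
                               max_bonds = max_bonds, singletons = singletons),
                 files = path)
  invisible(path)
}

# random connected heavy-atom graph: grow a random tree, then possibly add a
# cycle-closing bond; element valences capped (C 4, N 3, O 2)
random_molgraph <- function(max_bonds) {
  n_bonds <- sample(2:max_bonds, 1L)
  val_cap <- c(C = 4L, N = 3L, O = 2L)
  repeat {
    n_atoms <- n_bonds + 1L
    el <- sample(c("C", "C", "C", "N", "O"), n_atoms, replace = TRUE)
    deg <- integer(n_atoms)
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
    ok <- TRUE
    for (v in 2:n_atoms) {
      cand <- which(deg[seq_len(v - 1L)] < val_cap[el[seq_len(v - 1L)]])
      if (!length(cand)) { ok <- FALSE; break }
      u <- if (length(cand) == 1L) cand else sample(cand, 1L)
      ord <- if (deg[u] + 2L <= val_cap[el[u]] && deg[v] + 2L <= val_cap[el[v]] &&
                 runif(1) < 0.2) 2L else 1L
      bonds[nrow(bonds) + 1L, ] <- list(u, v, ord)
      deg[u] <- deg[u] + ord; deg[v] <- deg[v] + ord
    }
    if (ok) return(as_molgraph(list(atoms = el, bonds = bonds)))
  }
}
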