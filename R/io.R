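# File formats: ensembles as TSV (object_id, assembly_index, copy_number),
# assembly DAGs as GraphML (via igraph) or versioned JSON, strings as
# FASTA/plain text, run manifests as JSON. TSV is the tabular default
# (no quoting ambiguity); machine output goes to files/stdout, logs to
# stderr.

#' Read an ensemble from TSV
#'
#' Expects columns `object_id`, `assembly_index`, `copy_number`. Malformed
#' rows are rejected with their line numbers.
#'
#' @param path TSV file path.
#' @return An `assembly_ensemble`.
#' @export
read_ensemble_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("object_id", "assembly_index", "copy_number")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(sprintf("ensemble TSV '%s' missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")))
  bad <- which(is.na(df$assembly_index) | df$assembly_index < 0 |
                 is.na(df$copy_number) | df$copy_number < 1)
  if (length(bad))
    stop(sprintf("invalid ensemble rows (line %s): assembly_index must be >= 0 and copy_number >= 1",
                 paste(bad + 1L, collapse = ", ")))  # +1 for the header line
  ensemble(df$object_id, df$assembly_index, df$copy_number)
}

#' Write an ensemble to TSV
#' @param ens An `assembly_ensemble`.
#' @param path Output path.
#' @return `path`, invisibly; `read_ensemble_tsv(write_ensemble_tsv(...))`
#'   round-trips.
#' @export
write_ensemble_tsv <- function(ens, path) {
  stopifnot(inherits(ens, "assembly_ensemble"))
  write.table(ens$records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export an assembly DAG
#'
#' GraphML export goes through igraph with node attributes `length` and
#' `flag` and edge attributes `left`/`right` (the two join operands). JSON
#' export uses a versioned schema and is byte-stable: export, reload and
#' re-export give identical files.
#'
#' @param dag An `assembly_dag` from [joint_assembly_space()].
#' @param path Output file path.
#' @param format `"graphml"` or `"json"`.
#' @return `path`, invisibly.
#' @export
export_dag <- function(dag, path, format = c("graphml", "json")) {
  stopifnot(inherits(dag, "assembly_dag"))
  format <- match.arg(format)
  if (format == "graphml") {
    ids <- sprintf("n%.0f", dag$nodes$length)
    gr <- igraph::make_empty_graph(n = 0, directed = TRUE)
    gr <- igraph::add_vertices(gr, nrow(dag$nodes), name = ids,
                               length = dag$nodes$length, flag = dag$nodes$flag)
    if (nrow(dag$edges)) {
      ep <- rbind(sprintf("n%.0f", dag$edges$from), sprintf("n%.0f", dag$edges$to))
      gr <- igraph::add_edges(gr, as.vector(ep),
                              left = dag$edges$left, right = dag$edges$right)
    }
    igraph::write_graph(gr, path, format = "graphml")
  } else {
    obj <- list(schema = "assembly-dag/1",
                nodes = data.frame(length = dag$nodes$length, flag = dag$nodes$flag),
                edges = dag$edges, approximate = dag$approximate)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Load an assembly DAG from its JSON export
#' @param path JSON file written by [export_dag()].
#' @return An `assembly_dag`.
#' @export
read_dag_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "assembly-dag/1"))
    stop(sprintf("unknown DAG schema in '%s'", path))
  edges <- as.data.frame(obj$edges)
  if (!nrow(edges)) edges <- data.frame(from = numeric(0), to = numeric(0),
                                        left = numeric(0), right = numeric(0))
  structure(list(nodes = as.data.frame(obj$nodes), edges = edges,
                 approximate = isTRUE(obj$approximate)), class = "assembly_dag")
}

#' Read string objects from FASTA or plain text
#'
#' FASTA files (leading `>`) give one object per record via Biostrings;
#' plain text gives one object per non-empty line.
#'
#' @param path Input file.
#' @return Named character vector of sequences.
#' @export
read_strings <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) && startsWith(first, ">")) {
    ss <- Biostrings::readBStringSet(path)
    setNames(as.character(ss), names(ss))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    setNames(lines, paste0("seq", seq_along(lines)))
  }
}

#' Write a reproducibility manifest
#'
#' Records the command, configuration snapshot, seed, package version,
#' timestamp and MD5 digests of the listed input/output files: enough to
#' re-run the computation and reproduce its outputs exactly.
#'
#' @param path Manifest output path (JSON).
#' @param command Character description of the invocation.
#' @param config List of configuration values (must include any seed used).
#' @param files Character vector of associated file paths to digest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, config, files = character(0)) {
  digests <- if (length(files))
    as.list(tools::md5sum(files[file.exists(files)])) else list()
  obj <- list(schema = "assembly-manifest/1", command = command,
              config = config,
              tool = list(package = "assemblyr",
                          version = as.character(packageVersion("assemblyr"))),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              file_md5 = digests)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write molecular graphs to an SDF (V2000) file
#'
#' @param mols List of molgraph objects (named for SDF record ids).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_molecules_sdf <- function(mols, path) {
  if (is.null(names(mols))) names(mols) <- paste0("mol", seq_along(mols))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(mols)) {
    g <- as_molgraph(mols[[k]])
    a <- g$payload$atoms; b <- g$payload$bonds
    ord <- ifelse(b$order == 4L, 4L, b$order)  # aromatic kept as type 4
    writeLines(c(names(mols)[k], "  assemblyr", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       length(a), nrow(b)), con)
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       0, 0, 0, a), con)
    writeLines(sprintf("%3d%3d%3d  0  0  0  0", b$i, b$j, ord), con)
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}
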