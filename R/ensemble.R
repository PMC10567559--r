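# The assembly equation on ensembles of objects with copy numbers:
#   A = sum_i exp(a_i) * (n_i - 1) / N_T
# over the N unique objects, with a_i the assembly index of object i, n_i its
# copy number and N_T the total object count. Singletons contribute nothing:
# only repeated production of a multi-step object signals a non-random
# (selective) generative process.

#' Construct an ensemble of objects with copy numbers
#'
#' @param object_id Character vector of unique object identifiers.
#' @param assembly_index Non-negative integer vector of assembly indices.
#' @param copy_number Positive integer vector of copy numbers. Fractional
#'   abundances are rounded down with a warning (copy numbers are counts).
#' @return An `assembly_ensemble`: list with `records` (data frame), `N`
#'   (unique object count) and `N_T` (total copies).
#' @examples
#' ens <- ensemble(c("x", "y"), c(1, 2), c(2, 3))
#' assembly_A(ens)  # (e + 2 e^2) / 5
#' @export
ensemble <- function(object_id, assembly_index, copy_number) {
  if (length(object_id) == 0L) stop("ensemble is empty: at least one record required")
  if (anyDuplicated(object_id)) stop("ensemble object ids must be unique")
  if (length(assembly_index) != length(object_id) ||
      length(copy_number) != length(object_id))
    stop("ensemble fields must have equal length")
  if (any(is.na(assembly_index)) || any(assembly_index < 0))
    stop("assembly indices must be non-negative")
  if (any(is.na(copy_number)) || any(copy_number < 1))
    stop("copy numbers must be >= 1 (unobserved objects are excluded from ensembles)")
  if (any(copy_number != floor(copy_number))) {
    warning("fractional copy numbers rounded down to integer counts")
    copy_number <- floor(copy_number)
  }
  rec <- data.frame(object_id = as.character(object_id),
                    assembly_index = as.numeric(assembly_index),
                    copy_number = as.numeric(copy_number),
                    stringsAsFactors = FALSE)
  structure(list(records = rec, N = nrow(rec), N_T = sum(rec$copy_number)),
            class = "assembly_ensemble")
}

#' @export
print.assembly_ensemble <- function(x, ...) {
  cat(sprintf("<assembly ensemble> N = %d unique objects, N_T = %s total copies, A = %.6g\n",
              x$N, format(x$N_T), assembly_A(x)))
  invisible(x)
}

#' Assembly of an ensemble (the assembly equation)
#'
#' Evaluates `A = sum_i exp(a_i) (n_i - 1) / N_T`. `A` is zero exactly when
#' every object is a singleton, grows linearly in any one copy number, and
#' exponentially in assembly index.
#'
#' @param ens An `assembly_ensemble` (see [ensemble()]).
#' @return Non-negative numeric scalar.
#' @export
assembly_A <- function(ens) {
  stopifnot(inherits(ens, "assembly_ensemble"))
  sum(assembly_contributions(ens))
}

#' Per-record contributions to ensemble assembly
#' @param ens An `assembly_ensemble`.
#' @return Named numeric vector, one term `exp(a_i) (n_i - 1) / N_T` per record.
#' @export
assembly_contributions <- function(ens) {
  stopifnot(inherits(ens, "assembly_ensemble"))
  r <- ens$records
  setNames(exp(r$assembly_index) * (r$copy_number - 1) / ens$N_T, r$object_id)
}

#' Build an ensemble from raw objects with multiplicity
#'
#' Canonicalizes and groups identical objects, assigns each unique object its
#' assembly index through `index_fn`, and assembles the copy-number records.
#'
#' @param objects A list (or vector) of raw objects of a common kind.
#' @param index_fn Function mapping a canonical `assembly_object` to its
#'   assembly index (default: the package's exact [assembly_index()]).
#' @param kind Object kind passed to [canonicalize()].
#' @return An `assembly_ensemble`.
#' @examples
#' ensemble_from_objects(c("AA", "AA", "A"), kind = "string")
#' @export
ensemble_from_objects <- function(objects,
                                  index_fn = function(o) assembly_index(o)$index,
                                  kind = "string") {
  if (length(objects) == 0L) stop("ensemble is empty: no objects supplied")
  objs <- lapply(objects, canonicalize, kind = kind)
  keys <- vapply(objs, function(o) {
    if (o$kind == "molgraph") molgraph_certificate(o) else as.character(o$payload)
  }, character(1))
  uk <- unique(keys)
  idx <- vapply(uk, function(k) {
    o <- objs[[match(k, keys)]]
    val <- tryCatch(index_fn(o),
                    error = function(e) stop(sprintf(
                      "assembly index failed for object '%s': %s",
                      substr(k, 1, 40), conditionMessage(e)), call. = FALSE))
    as.numeric(val)
  }, numeric(1))
  ids <- vapply(uk, function(k) {
    o <- objs[[match(k, keys)]]
    if (o$kind == "homopolymer") paste0("len", format(o$payload))
    else if (o$kind == "string") o$payload
    else substr(k, 1, 40)
  }, character(1))
  ensemble(ids, idx, as.numeric(table(keys)[uk]))
}
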