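#' Global protein index over several species
#'
#' Maintains the ordered concatenation of all species' proteins that every
#' matrix in the pipeline (adjacency, homology, similarity, labels) is
#' aligned to. Species keep their input order; within a species, proteins
#' keep the order in which they were supplied.
#'
#' @param proteins named list: species id -> character vector of protein IDs
#'   (unique within and across species).
#' @return A `protein_index` object with fields `species_ids`,
#'   `proteins_per_species`, `global_offset` (0-based start of each species'
#'   block), `sizes` and `total` (N, the summed proteome size).
#' @examples
#' idx <- protein_index(list(a = c("a.p1", "a.p2"), b = c("b.p1")))
#' idx$total
#' @export
protein_index <- function(proteins) {
  stopifnot(is.list(proteins), length(proteins) >= 1)
  if (is.null(names(proteins)) || any(names(proteins) == "")) {
    stop("every species must be named")
  }
  proteins <- lapply(proteins, as.character)
  all_ids <- unlist(proteins, use.names = FALSE)
  dup <- all_ids[duplicated(all_ids)]
  if (length(dup) > 0) {
    stop("protein IDs must be unique across species; duplicated: ",
         paste(utils::head(unique(dup), 5), collapse = ", "))
  }
  sizes <- vapply(proteins, length, integer(1))
  offsets <- cumsum(c(0L, utils::head(sizes, -1L)))
  names(offsets) <- names(proteins)
  structure(list(
    species_ids          = names(proteins),
    proteins_per_species = proteins,
    global_offset        = offsets,
    sizes                = sizes,
    total                = sum(sizes)
  ), class = "protein_index")
}

#' @export
print.protein_index <- function(x, ...) {
  cat("protein_index:", length(x$species_ids), "species,",
      x$total, "proteins\n")
  for (sp in x$species_ids) {
    cat("  ", sp, ": n =", x$sizes[[sp]],
        " offset =", x$global_offset[[sp]], "\n")
  }
  invisible(x)
}

#' Map (species, local index) to the global index
#'
#' @param index a [protein_index()].
#' @param species_id species identifier.
#' @param local 1-based positions within the species block (default all).
#' @return 1-based global positions.
#' @export
global_index <- function(index, species_id, local = NULL) {
  stopifnot(inherits(index, "protein_index"))
  if (!species_id %in% index$species_ids) stop("unknown species: ", species_id)
  n <- index$sizes[[species_id]]
  if (is.null(local)) local <- seq_len(n)
  stopifnot(all(local >= 1L), all(local <= n))
  index$global_offset[[species_id]] + local
}

#' Resolve protein IDs to global indices
#'
#' @param index a [protein_index()].
#' @param ids character vector of protein IDs.
#' @return integer vector of 1-based global positions; NA where unresolvable.
#' @export
resolve_proteins <- function(index, ids) {
  all_ids <- unlist(index$proteins_per_species, use.names = FALSE)
  match(ids, all_ids)
}

#' Species membership of global indices
#'
#' @param index a [protein_index()].
#' @param global 1-based global positions.
#' @return character vector of species ids.
#' @export
species_of <- function(index, global) {
  breaks <- c(index$global_offset, index$total)
  ix <- findInterval(global - 1L, index$global_offset)
  index$species_ids[ix]
}

#' All protein IDs in global order
#' @param index a [protein_index()].
#' @return character vector of length `index$total`.
#' @export
all_proteins <- function(index) {
  unlist(index$proteins_per_species, use.names = FALSE)
}

#' Rows/columns of one species inside a global matrix
#' @param index a [protein_index()].
#' @param species_id species identifier.
#' @return integer vector of global positions of that species' block.
#' @export
species_block <- function(index, species_id) {
  global_index(index, species_id)
}
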