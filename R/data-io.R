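#' Read a weighted PPI edge list into an adjacency matrix
#'
#' Accepts STRING `protein.links.detailed`-style TSV files: a header naming
#' the two endpoint columns (`protein1`, `protein2`) and one or more score
#' columns. STRING's integer scores (0-1000) are auto-detected and divided
#' by 1000; float scores already in \[0,1\] pass through unchanged. The
#' matrix is symmetrized by taking the maximum of the two directed entries
#' and self-edges are dropped. Proteins present in the index but absent
#' from the file get all-zero rows (network-isolated proteins).
#'
#' @param path TSV edge list with header.
#' @param species_id which species this file describes.
#' @param index a [protein_index()]; defines row order.
#' @param channel score column to use (default `"experimental"`, the STRING
#'   channel backed by direct experimental evidence).
#' @return `adjacency_matrix` object: list with `species_id` and `matrix`
#'   (n_i x n_i symmetric, zero diagonal, entries in \[0,1\]).
#' @export
read_network <- function(path, species_id, index, channel = "experimental") {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1:2))
  n <- index$sizes[[species_id]]
  ids <- index$proteins_per_species[[species_id]]
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(dt) > 0) {
    if (!channel %in% names(dt)) {
      stop("channel column '", channel, "' not found in ", path,
           " (have: ", paste(names(dt), collapse = ", "), ")")
    }
    w <- as.numeric(dt[[channel]])
    # STRING dialect: integer scores on a 0-1000 scale
    if (is.integer(dt[[channel]]) || all(w == round(w) & w > 1, na.rm = TRUE)) {
      w <- w / 1000
    }
    i <- match(dt[[1]], ids)
    j <- match(dt[[2]], ids)
    bad <- is.na(i) | is.na(j)
    if (any(bad)) {
      warning(sum(bad), " edges with proteins not in the index for species ",
              species_id, " were skipped")
    }
    keep <- !bad & i != j
    # max-symmetrization: collapse both directions onto the upper triangle
    ed <- data.table::data.table(i = pmin(i[keep], j[keep]),
                                 j = pmax(i[keep], j[keep]),
                                 w = w[keep])
    if (nrow(ed) > 0) {
      ed <- ed[, list(w = max(w)), by = c("i", "j")]
      A[cbind(ed$i, ed$j)] <- ed$w
      A[cbind(ed$j, ed$i)] <- ed$w
    }
  }
  adjacency_matrix(species_id, A)
}

#' Construct an adjacency matrix object
#'
#' @param species_id species identifier.
#' @param matrix symmetric nonnegative matrix with zero diagonal.
#' @return `adjacency_matrix` object.
#' @export
adjacency_matrix <- function(species_id, matrix) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  if (any(matrix < 0)) stop("adjacency entries must be nonnegative")
  if (any(abs(matrix - t(matrix)) > 1e-12)) stop("adjacency must be symmetric")
  diag(matrix) <- 0
  structure(list(species_id = species_id, matrix = matrix),
            class = "adjacency_matrix")
}

#' Write an adjacency matrix back to the edge-list dialect
#'
#' Upper-triangle nonzero entries only, float scores. `read_network()`
#' composed with `write_network()` is the identity on symmetrized matrices.
#'
#' @param A an `adjacency_matrix`.
#' @param path output TSV path.
#' @param index a [protein_index()].
#' @export
write_network <- function(A, path, index) {
  m <- A$matrix
  ids <- index$proteins_per_species[[A$species_id]]
  ut <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
  dt <- data.table::data.table(
    protein1 = ids[ut[, 1]],
    protein2 = ids[ut[, 2]],
    experimental = m[ut]
  )
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a protein -> GO term annotation table
#'
#' Expects a TSV with columns `protein`, `go_term`, `branch`, `evidence_code`
#' (a GAF 2.x column mapping can be supplied via `gaf_cols` naming the
#' positional columns to use). Rows with branches outside MF/BP/CC are
#' skipped and counted; exact duplicate (protein, term, branch, evidence)
#' rows are dropped; records whose protein is not in the index are dropped
#' with a warning, and the read aborts if more than half the records are
#' unresolvable (an ID-namespace mismatch).
#'
#' @param path annotation TSV.
#' @param index a [protein_index()].
#' @param gaf_cols optional integer vector of length 4 giving the column
#'   positions of (protein, term, branch, evidence) in a headerless GAF-like
#'   file; default NULL reads named columns.
#' @return `annotation_table`: data.table with columns `protein`, `go_term`,
#'   `branch`, `evidence_code`, `global` (resolved index).
#' @export
read_annotations <- function(path, index, gaf_cols = NULL) {
  if (is.null(gaf_cols)) {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            colClasses = "character")
    need <- c("protein", "go_term", "branch", "evidence_code")
    if (!all(need %in% names(dt))) {
      stop("annotation file must have columns: ", paste(need, collapse = ", "))
    }
    dt <- dt[, need, with = FALSE]
  } else {
    stopifnot(length(gaf_cols) == 4)
    raw <- data.table::fread(path, sep = "\t", header = FALSE,
                             colClasses = "character")
    dt <- raw[, gaf_cols, with = FALSE]
    data.table::setnames(dt, c("protein", "go_term", "branch", "evidence_code"))
  }
  n0 <- nrow(dt)
  dt <- dt[dt$branch %in% c("MF", "BP", "CC"), ]
  n_badbranch <- n0 - nrow(dt)
  if (n_badbranch > 0) {
    warning(n_badbranch, " records with unknown GO branch skipped")
  }
  dt <- unique(dt)
  dt$global <- resolve_proteins(index, dt$protein)
  n_unres <- sum(is.na(dt$global))
  if (nrow(dt) > 0 && n_unres > nrow(dt) / 2) {
    stop(n_unres, "/", nrow(dt), " annotation proteins unresolvable; ",
         "likely an ID-namespace mismatch with the network files")
  }
  if (n_unres > 0) {
    warning(n_unres, " annotation records with unresolvable proteins dropped")
    dt <- dt[!is.na(dt$global), ]
  }
  for (br in intersect(c("MF", "BP", "CC"), unique(dt$branch))) {
    message("annotations: ", br, ": ", sum(dt$branch == br), " records")
  }
  structure(dt, class = c("annotation_table", class(dt)))
}

#' Build an annotation table from an in-memory data frame
#' @param df data frame with columns protein, go_term, branch, evidence_code.
#' @param index a [protein_index()].
#' @return `annotation_table`.
#' @export
annotation_table <- function(df, index) {
  dt <- data.table::as.data.table(df)[, c("protein", "go_term", "branch",
                                          "evidence_code"), with = FALSE]
  dt <- unique(dt)
  dt$global <- resolve_proteins(index, dt$protein)
  dt <- dt[!is.na(dt$global), ]
  structure(dt, class = c("annotation_table", class(dt)))
}

#' Filter GO terms to a per-species frequency window and build labels
#'
#' A term is retained when, in at least one species, the fraction of that
#' species' indexed proteins carrying it (counting every evidence code,
#' including IEA) lies in the closed interval \[`lo`, `hi`\]. Rare terms are
#' statistically untrainable and very frequent terms are shallow, general
#' ontology ancestors; the window keeps the specific middle. Proteins left
#' with no annotation among the kept terms are masked out of training and
#' evaluation.
#'
#' @param annotations an `annotation_table`.
#' @param index a [protein_index()].
#' @param branch GO branch, one of "MF", "BP", "CC".
#' @param lo,hi inclusive frequency bounds (defaults 0.005 and 0.05).
#' @param evidence optional character vector restricting which evidence
#'   codes contribute *positives* to the matrix (the frequency window is
#'   always computed over all codes); NULL keeps all.
#' @return `label_matrix`: list with `branch`, `term_ids`, `matrix`
#'   (N x c binary over the whole index) and `mask` (length-N logical,
#'   TRUE for proteins kept).
#' @export
filter_terms <- function(annotations, index, branch,
                         lo = 0.005, hi = 0.05, evidence = NULL) {
  ann <- annotations[annotations$branch == branch, ]
  if (nrow(ann) == 0) stop("no annotations for branch ", branch)
  sp <- species_of(index, ann$global)
  # per-species fraction of indexed proteins annotated with each term
  freq <- data.table::as.data.table(
    list(term = ann$go_term, species = sp, global = ann$global))
  freq <- unique(freq)  # distinct (term, protein)
  counts <- freq[, list(n = length(unique(global))),
                 by = c("term", "species")]
  counts$frac <- counts$n / as.numeric(index$sizes[counts$species])
  kept <- sort(unique(counts$term[counts$frac >= lo & counts$frac <= hi]))
  if (length(kept) == 0) {
    rep_tab <- counts[order(counts$term), ]
    stop("no GO terms fall in the [", lo, ", ", hi, "] frequency window; ",
         "per-term per-species fractions: ",
         paste(sprintf("%s/%s=%.4f", rep_tab$term, rep_tab$species,
                       rep_tab$frac), collapse = "; "))
  }
  label_matrix_from_annotations(ann, index, branch, kept, evidence)
}

#' Build a label matrix over a fixed term set
#' @keywords internal
label_matrix_from_annotations <- function(ann, index, branch, term_ids,
                                          evidence = NULL) {
  use <- ann[ann$go_term %in% term_ids, ]
  mask <- rep(FALSE, index$total)
  mask[unique(use$global)] <- TRUE  # mask from any-evidence annotations
  if (!is.null(evidence)) use <- use[use$evidence_code %in% evidence, ]
  y <- matrix(0L, index$total, length(term_ids),
              dimnames = list(all_proteins(index), term_ids))
  if (nrow(use) > 0) {
    y[cbind(use$global, match(use$go_term, term_ids))] <- 1L
  }
  structure(list(branch = branch, term_ids = term_ids,
                 matrix = y, mask = mask),
            class = "label_matrix")
}

#' Save a run's matrices and index to a container directory
#'
#' A plain-text hierarchical store: one directory with a JSON manifest
#' (`manifest.json`, holding the index and dataset names) and one TSV per
#' named matrix. Stable dataset names used by the pipeline:
#' `isorank/<i>_<j>` for pair blocks, `block_S` for the assembled matrix,
#' `labels/<branch>` for label matrices.
#'
#' @param store directory path (created if missing).
#' @param index a [protein_index()].
#' @param datasets named list of matrices.
#' @export
save_store <- function(store, index, datasets = list()) {
  dir.create(store, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    species_ids = index$species_ids,
    proteins = index$proteins_per_species,
    datasets = names(datasets)
  )
  jsonlite::write_json(manifest, file.path(store, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  for (nm in names(datasets)) {
    f <- file.path(store, paste0(gsub("/", "__", nm), ".tsv"))
    data.table::fwrite(data.table::as.data.table(datasets[[nm]]), f,
                       sep = "\t")
  }
  invisible(store)
}

#' Load a container directory written by [save_store()]
#' @param store directory path.
#' @return list with `index` and `datasets` (named list of matrices).
#' @export
load_store <- function(store) {
  manifest <- jsonlite::read_json(file.path(store, "manifest.json"),
                                  simplifyVector = TRUE)
  idx <- protein_index(as.list(manifest$proteins)[manifest$species_ids])
  datasets <- list()
  for (nm in manifest$datasets) {
    f <- file.path(store, paste0(gsub("/", "__", nm), ".tsv"))
    datasets[[nm]] <- as.matrix(data.table::fread(f, sep = "\t"))
  }
  list(index = idx, datasets = datasets)
}
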