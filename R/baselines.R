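#' CAFA BLAST annotation-transfer baseline
#'
#' Scores a term for a query protein by the highest percent identity
#' (scaled to \[0,1\]) among its BLAST hits to training proteins carrying
#' that term; zero when no annotated hit exists.
#'
#' @param identities an [identity_table()].
#' @param train_labels binary label matrix over the global index (training
#'   positives, any evidence code).
#' @param test_proteins global indices of the query proteins.
#' @param train_proteins global indices eligible as annotation sources
#'   (default: every protein with at least one positive label).
#' @return score matrix, `length(test_proteins)` x c, entries in \[0,1\].
#' @export
blast_transfer <- function(identities, train_labels, test_proteins,
                           train_proteins = NULL) {
  Y <- if (inherits(train_labels, "label_matrix")) {
    train_labels$matrix
  } else {
    train_labels
  }
  if (is.null(train_proteins)) train_proteins <- which(rowSums(Y) > 0)
  scores <- matrix(0, length(test_proteins), ncol(Y),
                   dimnames = list(NULL, colnames(Y)))
  hits <- identities[identities$a %in% test_proteins &
                       identities$b %in% train_proteins, ]
  if (nrow(hits) == 0) return(scores)
  for (qi in seq_along(test_proteins)) {
    h <- hits[hits$a == test_proteins[qi], ]
    if (nrow(h) == 0) next
    w <- h$pident / 100
    Yh <- Y[h$b, , drop = FALSE]
    scores[qi, ] <- apply(Yh * w, 2, max)
  }
  scores
}

#' Training-set variants for the ablation benchmarks
#'
#' The three reduced versions of the multispecies model, which disentangle
#' the effect of extra training examples from the effect of extra feature
#' columns:
#' \describe{
#'   \item{full}{all training proteins, full-width S rows.}
#'   \item{subsampled}{a random subset of the full training rows,
#'     equal in count to the target species' own training proteins.}
#'   \item{single_annotations}{only the target species' training
#'     rows, still with full-width multispecies features.}
#'   \item{single_species}{the target species' rows restricted to
#'     its own diagonal block — the purely single-species model.}
#' }
#' The two single-* variants use identical label subsets; only the feature
#' columns differ.
#'
#' @param variant variant name (see above).
#' @param S N x N block similarity matrix.
#' @param labels training `label_matrix` (or plain binary matrix).
#' @param index a [protein_index()].
#' @param species_id target species.
#' @param train_global global indices of all eligible training proteins
#'   (masked-in, test held out).
#' @param seed RNG seed for the subsampling variant.
#' @return list with `features`, `labels` (aligned matrices), `rows`
#'   (global indices used) and `feature_cols` (column indices of S kept).
#' @export
variant_training_set <- function(variant, S, labels, index, species_id,
                                 train_global, seed = 1) {
  Y <- if (inherits(labels, "label_matrix")) labels$matrix else labels
  blk <- species_block(index, species_id)
  own_train <- intersect(train_global, blk)
  all_cols <- seq_len(ncol(S))
  pick <- switch(
    variant,
    full = list(rows = train_global, cols = all_cols),
    subsampled = {
      if (length(own_train) > length(train_global)) {
        stop("subsample count exceeds available training rows")
      }
      set.seed(seed)
      list(rows = sort(sample(train_global, length(own_train))),
           cols = all_cols)
    },
    single_annotations = list(rows = own_train, cols = all_cols),
    single_species = list(rows = own_train, cols = blk),
    stop("unknown variant: ", variant)
  )
  list(features = S[pick$rows, pick$cols, drop = FALSE],
       labels = Y[pick$rows, , drop = FALSE],
       rows = pick$rows,
       feature_cols = pick$cols)
}
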