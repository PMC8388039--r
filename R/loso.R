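#' IsoRank against a species with no network
#'
#' For a left-out organism the identity matrix stands in for its unknown
#' PPI network, so the recurrence reduces to
#' `S <- alpha * t(Ahat_i) %*% S + (1 - alpha) * R`.
#'
#' @param A_i adjacency matrix of a species with a known network.
#' @param R_i_test homology matrix (n_i x n_test) between species i and the
#'   left-out species.
#' @param alpha,tol,max_iter see [isorank_pair()].
#' @return `isorank_matrix` of dimension n_i x n_test.
#' @export
isorank_to_missing <- function(A_i, R_i_test, alpha = 0.6, tol = 1e-6,
                               max_iter = 50L) {
  if (inherits(R_i_test, "homology_matrix")) R_i_test <- R_i_test$matrix
  n_test <- ncol(R_i_test)
  isorank_pair(A_i, diag(n_test), R_i_test, alpha = alpha, tol = tol,
               max_iter = max_iter)
}

#' Impute a proxy network by one-mode projection
#'
#' Each contributing species' cross-similarity block `S_i,test` is a
#' bipartite similarity between its proteins and the left-out species'
#' proteins; the one-mode projection `t(S) %*% S` connects left-out
#' proteins through their shared neighbors in species i. The imputed
#' network is the element-wise mean of the contributing projections (a
#' mean of Gram matrices, hence positive semidefinite before the diagonal
#' is zeroed). The diagonal is zeroed by default: self-similarity is not
#' an interaction.
#'
#' @param S_blocks list of `isorank_matrix` (or plain n_i x n_test
#'   matrices), one per contributing species.
#' @param species_id identifier of the left-out species.
#' @param zero_diagonal drop the projection diagonal (default TRUE; keep it
#'   with FALSE for sensitivity checks).
#' @return `imputed_network`: list with `species_id`, `matrix`
#'   (n_test x n_test), `source_species` count.
#' @export
project_network <- function(S_blocks, species_id = "test",
                            zero_diagonal = TRUE) {
  if (length(S_blocks) == 0) stop("no contributing species")
  mats <- lapply(S_blocks, function(b) {
    if (inherits(b, "isorank_matrix")) b$matrix else b
  })
  n_test <- ncol(mats[[1]])
  if (!all(vapply(mats, ncol, integer(1)) == n_test)) {
    stop("all blocks must share the left-out species' column count")
  }
  acc <- matrix(0, n_test, n_test)
  for (m in mats) acc <- acc + crossprod(m)
  A <- acc / length(mats)
  A <- (A + t(A)) / 2  # crossprod is symmetric up to rounding
  if (zero_diagonal) diag(A) <- 0
  structure(list(species_id = species_id, matrix = A,
                 source_species = length(mats)),
            class = "imputed_network")
}

#' Intra-species IsoRank on an imputed network
#'
#' Completes the left-out species' feature rows: the imputed proxy network
#' is aligned with itself, combined with the species' own self-BLAST
#' homology. The proxy is not rescaled beforehand — [isorank_pair()]
#' row-normalizes internally, so the raw Gram magnitudes only determine
#' the zero/nonzero row structure.
#'
#' @param A_hat_test an `imputed_network` (or plain matrix).
#' @param R_test_test intra-species homology matrix of the left-out species.
#' @param alpha,tol,max_iter see [isorank_pair()].
#' @return `isorank_matrix` of dimension n_test x n_test.
#' @export
self_similarity_for_missing <- function(A_hat_test, R_test_test,
                                        alpha = 0.6, tol = 1e-6,
                                        max_iter = 50L) {
  if (inherits(A_hat_test, "imputed_network")) A_hat_test <- A_hat_test$matrix
  isorank_pair(A_hat_test, A_hat_test, R_test_test, alpha = alpha,
               tol = tol, max_iter = max_iter)
}

#' Assemble the full similarity matrix with one species' network imputed
#'
#' Runs the complete imputation: for every training species i, computes
#' `S_i,test` with the identity standing in for the left-out network, takes
#' the one-mode projection mean as the proxy network, aligns the proxy with
#' itself, and places all blocks (the training species' mutual blocks
#' unchanged) into the global layout of the index. Row features of the
#' left-out proteins therefore live in the same column space as the
#' training rows.
#'
#' @param networks named list of `adjacency_matrix` for the training
#'   species only (the left-out species' network, if supplied, is ignored
#'   and never read).
#' @param R_blocks named list of `homology_matrix` keyed `"<i>|<j>"` over
#'   all species including the left-out one.
#' @param index a [protein_index()] over all species.
#' @param leave_out species id to impute.
#' @param alpha,tol,max_iter see [isorank_pair()].
#' @param zero_diagonal see [project_network()].
#' @return list with `S` (a `block_similarity` over the full index),
#'   `imputed` (the `imputed_network`).
#' @export
loso_similarity <- function(networks, R_blocks, index, leave_out,
                            alpha = 0.6, tol = 1e-6, max_iter = 50L,
                            zero_diagonal = TRUE) {
  sp <- index$species_ids
  if (!leave_out %in% sp) stop("leave_out species not in index")
  train_sp <- setdiff(sp, leave_out)
  pair_key <- function(a, b) {
    ia <- match(a, sp); ib <- match(b, sp)
    if (ia <= ib) paste(a, b, sep = "|") else paste(b, a, sep = "|")
  }
  get_R <- function(a, b) {
    key <- pair_key(a, b)
    R <- R_blocks[[key]]
    if (is.null(R)) stop("missing homology block ", key)
    m <- if (inherits(R, "homology_matrix")) R$matrix else R
    # stored block is oriented (min-index, max-index); orient to (a, b)
    if (match(a, sp) <= match(b, sp)) m else t(m)
  }
  blocks <- list()
  # training species' mutual blocks: the ordinary pipeline
  for (a in seq_along(sp)) {
    for (b in a:length(sp)) {
      if (sp[a] == leave_out || sp[b] == leave_out) next
      key <- paste(sp[a], sp[b], sep = "|")
      blocks[[key]] <- isorank_pair(networks[[sp[a]]], networks[[sp[b]]],
                                    get_R(sp[a], sp[b]), alpha = alpha,
                                    tol = tol, max_iter = max_iter)
    }
  }
  # cross blocks to the left-out species, with identity as its network
  cross <- list()
  for (i in train_sp) {
    cross[[i]] <- isorank_to_missing(networks[[i]], get_R(i, leave_out),
                                     alpha = alpha, tol = tol,
                                     max_iter = max_iter)
    key <- pair_key(i, leave_out)
    blocks[[key]] <- if (match(i, sp) <= match(leave_out, sp)) {
      cross[[i]]
    } else {
      structure(list(matrix = t(cross[[i]]$matrix), alpha = alpha),
                class = "isorank_matrix")
    }
  }
  imputed <- project_network(cross, species_id = leave_out,
                             zero_diagonal = zero_diagonal)
  blocks[[paste(leave_out, leave_out, sep = "|")]] <-
    self_similarity_for_missing(imputed, get_R(leave_out, leave_out),
                                alpha = alpha, tol = tol,
                                max_iter = max_iter)
  list(S = assemble_block(blocks, index), imputed = imputed)
}
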