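#' Row-normalize an adjacency matrix
#'
#' Each nonzero row is divided by its sum; all-zero rows stay zero. No
#' teleportation or self-loop is added for isolated proteins: their
#' similarity is then driven entirely by the homology term of the IsoRank
#' recurrence, which is the intended semantics for network-isolated nodes.
#'
#' @param A matrix (or `adjacency_matrix`) with nonnegative entries.
#' @return matrix whose nonzero rows sum to 1.
#' @export
row_normalize <- function(A) {
  if (inherits(A, "adjacency_matrix")) A <- A$matrix
  if (any(A < 0)) stop("negative entries in adjacency matrix")
  rs <- rowSums(A)
  nz <- rs > 0
  A[nz, ] <- A[nz, , drop = FALSE] / rs[nz]
  A
}

#' IsoRank similarity between two species' networks
#'
#' Iterates the diffusion recurrence
#' `S <- alpha * t(Ahat_i) %*% S %*% Ahat_j + (1 - alpha) * R`
#' where `Ahat` are the row-normalized adjacency matrices and `R` the
#' scaled homology matrix, starting from the rectangular identity, until
#' the Frobenius norm of the difference between consecutive iterates drops
#' below `tol`. For `alpha < 1` the map is an affine contraction, so the
#' fixed point is unique and independent of the start. The intra-species
#' matrix is the same call with both arguments equal.
#'
#' @param A_i,A_j adjacency matrices (objects or plain matrices); these are
#'   row-normalized internally.
#' @param R homology matrix for the pair (object or plain n_i x n_j matrix),
#'   entries in \[0,1\].
#' @param alpha diffusion weight in \[0,1): the share of similarity drawn
#'   from network neighbors rather than direct homology (default 0.6).
#' @param tol Frobenius-norm convergence tolerance (default 1e-6).
#' @param max_iter iteration cap (default 50).
#' @param S0 optional starting matrix (default rectangular identity).
#' @return `isorank_matrix`: list with `matrix`, `alpha`, `iterations_run`,
#'   `final_residual`, `converged`.
#' @export
isorank_pair <- function(A_i, A_j, R, alpha = 0.6, tol = 1e-6,
                         max_iter = 50L, S0 = NULL) {
  if (inherits(A_i, "adjacency_matrix")) A_i <- A_i$matrix
  if (inherits(A_j, "adjacency_matrix")) A_j <- A_j$matrix
  if (inherits(R, "homology_matrix")) R <- R$matrix
  stopifnot(alpha >= 0, alpha < 1)
  ni <- nrow(A_i); nj <- nrow(A_j)
  if (nrow(R) != ni || ncol(R) != nj) {
    stop("R must be ", ni, " x ", nj, ", got ", nrow(R), " x ", ncol(R))
  }
  Ai <- row_normalize(A_i)
  Aj <- row_normalize(A_j)
  if (is.null(S0)) {
    S <- matrix(0, ni, nj)
    k <- seq_len(min(ni, nj))
    S[cbind(k, k)] <- 1
  } else {
    S <- S0
  }
  resid <- Inf
  iters <- 0L
  while (iters < max_iter) {
    S_new <- alpha * crossprod(Ai, S %*% Aj) + (1 - alpha) * R
    if (!all(is.finite(S_new))) stop("non-finite IsoRank iterate")
    resid <- sqrt(sum((S_new - S)^2))
    S <- S_new
    iters <- iters + 1L
    if (resid < tol) break
  }
  structure(list(matrix = S, alpha = alpha, iterations_run = iters,
                 final_residual = resid, converged = resid < tol),
            class = "isorank_matrix")
}

#' Compute IsoRank blocks for every species pair
#'
#' Pair computations are independent and deterministic; blocks can be
#' computed in any order.
#'
#' @param networks named list of `adjacency_matrix` objects (one per
#'   species, names = species ids in index order).
#' @param R_blocks named list of `homology_matrix` objects keyed
#'   `"<i>|<j>"` for every unordered pair including self-pairs (as built by
#'   [all_R_blocks()]).
#' @param index a [protein_index()].
#' @param alpha,tol,max_iter see [isorank_pair()].
#' @return named list of `isorank_matrix` keyed `"<i>|<j>"` for i <= j in
#'   species order.
#' @export
isorank_all_pairs <- function(networks, R_blocks, index, alpha = 0.6,
                              tol = 1e-6, max_iter = 50L) {
  sp <- index$species_ids
  out <- list()
  for (a in seq_along(sp)) {
    for (b in a:length(sp)) {
      key <- paste(sp[a], sp[b], sep = "|")
      if (is.null(R_blocks[[key]])) stop("missing homology block ", key)
      out[[key]] <- isorank_pair(networks[[sp[a]]], networks[[sp[b]]],
                                 R_blocks[[key]], alpha = alpha,
                                 tol = tol, max_iter = max_iter)
    }
  }
  out
}

#' Build homology matrices for every species pair from one hit table
#'
#' @param hits a `blast_hits` table covering all pairs (self-pairs too).
#' @param index a [protein_index()].
#' @param cutoff,eps,scale_max see [build_R()].
#' @return named list of `homology_matrix` keyed `"<i>|<j>"`, i <= j.
#' @export
all_R_blocks <- function(hits, index, cutoff = 1e-3, eps = 1e-180,
                         scale_max = -log(eps)) {
  sp <- index$species_ids
  out <- list()
  for (a in seq_along(sp)) {
    for (b in a:length(sp)) {
      key <- paste(sp[a], sp[b], sep = "|")
      out[[key]] <- build_R(hits, index, c(sp[a], sp[b]), cutoff = cutoff,
                            eps = eps, scale_max = scale_max)
    }
  }
  out
}

#' Assemble the full block similarity matrix S
#'
#' Intra-species IsoRank matrices form the diagonal blocks; each
#' inter-species block (i, j) is placed at species i's rows and species j's
#' columns, with its transpose mirrored at (j, i), so the result is
#' symmetric by construction. Row k of the result is the feature vector of
#' global protein k.
#'
#' @param S_blocks named list of `isorank_matrix` keyed `"<i>|<j>"` for
#'   every i <= j pair in species order (missing blocks are fatal).
#' @param index a [protein_index()].
#' @return `block_similarity`: list with `matrix` (N x N), `index`, `alpha`.
#' @export
assemble_block <- function(S_blocks, index) {
  sp <- index$species_ids
  missing <- character(0)
  for (a in seq_along(sp)) {
    for (b in a:length(sp)) {
      key <- paste(sp[a], sp[b], sep = "|")
      if (is.null(S_blocks[[key]])) missing <- c(missing, key)
    }
  }
  if (length(missing) > 0) {
    stop("missing IsoRank blocks: ", paste(missing, collapse = ", "))
  }
  N <- index$total
  S <- matrix(0, N, N, dimnames = list(all_proteins(index),
                                       all_proteins(index)))
  alpha <- NULL
  for (a in seq_along(sp)) {
    for (b in a:length(sp)) {
      key <- paste(sp[a], sp[b], sep = "|")
      blk <- S_blocks[[key]]
      m <- if (inherits(blk, "isorank_matrix")) blk$matrix else blk
      if (is.null(alpha) && inherits(blk, "isorank_matrix")) {
        alpha <- blk$alpha
      }
      ri <- species_block(index, sp[a])
      cj <- species_block(index, sp[b])
      if (a == b) {
        # diagonal block: symmetrize to erase rounding asymmetry from the
        # finite iteration (exact symmetry is a structural invariant of S)
        S[ri, cj] <- (m + t(m)) / 2
      } else {
        S[ri, cj] <- m
        S[cj, ri] <- t(m)
      }
    }
  }
  structure(list(matrix = S, index = index, alpha = alpha),
            class = "block_similarity")
}
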