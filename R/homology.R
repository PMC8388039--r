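#' Read BLAST tabular output (outfmt 6)
#'
#' Twelve-column BLAST tabular dialect: qseqid, sseqid, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore. Only
#' query, subject, pident and evalue are used. Multiple HSPs for a
#' (query, subject) pair are collapsed to the minimum e-value and maximum
#' percent identity; hits whose endpoints cannot be resolved in the index
#' are dropped and counted. Self-hits are retained: they supply the
#' diagonal of the intra-species homology matrices.
#'
#' @param path BLAST tabular TSV (no header).
#' @param index a [protein_index()].
#' @return `blast_hits`: data.table with columns `q`, `s` (global indices),
#'   `pident`, `evalue`.
#' @export
read_blast <- function(path, index) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          colClasses = list(character = 1:2))
  if (ncol(dt) < 12) stop("expected >= 12 BLAST tabular columns, got ",
                          ncol(dt))
  hits <- data.table::data.table(
    qid = dt[[1]], sid = dt[[2]],
    pident = suppressWarnings(as.numeric(dt[[3]])),
    evalue = suppressWarnings(as.numeric(dt[[11]]))
  )
  bad_num <- !is.finite(hits$evalue) | !is.finite(hits$pident)
  if (any(bad_num)) {
    warning(sum(bad_num), " BLAST rows with non-numeric fields skipped")
    hits <- hits[!bad_num, ]
  }
  hits$q <- resolve_proteins(index, hits$qid)
  hits$s <- resolve_proteins(index, hits$sid)
  unres <- is.na(hits$q) | is.na(hits$s)
  if (any(unres)) {
    warning(sum(unres), " BLAST hits with unresolvable proteins dropped")
    hits <- hits[!unres, ]
  }
  # collapse HSPs: best (lowest) e-value, best (highest) identity per pair
  hits <- hits[, list(pident = max(pident), evalue = min(evalue)),
               by = c("q", "s")]
  structure(hits[, c("q", "s", "pident", "evalue"), with = FALSE],
            class = c("blast_hits", "data.table", "data.frame"))
}

#' Build the scaled homology matrix R for one species pair
#'
#' Entries are `-log` transformed e-values mapped into \[0,1\]:
#' `min(1, -ln(max(evalue, eps)) / scale_max)` for hits passing the e-value
#' cutoff, 0 otherwise. `eps` floors e-values reported as exactly 0, and
#' `scale_max = -ln(eps)` by default, one global constant shared by every
#' species pair so that homology strength is comparable across blocks of
#' the assembled similarity matrix. The natural log is used; any base
#' cancels in the ratio. BLAST asymmetry is resolved per unordered protein
#' pair by the stronger (smaller) e-value of the two directions, which
#' makes `R_ji = t(R_ij)` hold by construction.
#'
#' @param hits a `blast_hits` table (any species; filtered internally).
#' @param index a [protein_index()].
#' @param pair character vector of two species ids (may be identical for
#'   the intra-species matrix).
#' @param cutoff maximum e-value for a hit to contribute (default 1e-3).
#' @param eps e-value floor (default 1e-180).
#' @param scale_max normalizing constant for the -log scores
#'   (default `-log(eps)`).
#' @return `homology_matrix`: list with `pair`, `matrix` (n_i x n_j, in
#'   \[0,1\]) and `scale_max`.
#' @export
build_R <- function(hits, index, pair, cutoff = 1e-3, eps = 1e-180,
                    scale_max = -log(eps)) {
  if (scale_max <= 0) stop("scale_max must be positive")
  i <- pair[1]; j <- pair[2]
  ni <- index$sizes[[i]]; nj <- index$sizes[[j]]
  oi <- index$global_offset[[i]]; oj <- index$global_offset[[j]]
  in_i <- function(g) g > oi & g <= oi + ni
  in_j <- function(g) g > oj & g <= oj + nj
  fwd <- hits[in_i(hits$q) & in_j(hits$s), ]
  bwd <- hits[in_j(hits$q) & in_i(hits$s), ]
  ed <- rbind(
    data.table::data.table(a = fwd$q - oi, b = fwd$s - oj, evalue = fwd$evalue),
    data.table::data.table(a = bwd$s - oi, b = bwd$q - oj, evalue = bwd$evalue)
  )
  R <- matrix(0, ni, nj)
  if (nrow(ed) > 0) {
    ed <- ed[, list(evalue = min(evalue)), by = c("a", "b")]
    ed <- ed[ed$evalue <= cutoff, ]
    if (nrow(ed) > 0) {
      val <- pmin(1, -log(pmax(ed$evalue, eps)) / scale_max)
      R[cbind(ed$a, ed$b)] <- val
    }
  }
  structure(list(pair = pair, matrix = R, scale_max = scale_max),
            class = "homology_matrix")
}

#' Percent-identity lookup for the BLAST annotation-transfer baseline
#'
#' Symmetric sparse map over unordered global protein pairs, max-merged
#' across the two BLAST directions.
#'
#' @param hits a `blast_hits` table.
#' @return `identity_table`: data.table with columns `a`, `b` (global,
#'   both orders present), `pident` in \[0,100\].
#' @export
identity_table <- function(hits) {
  ed <- data.table::data.table(a = pmin(hits$q, hits$s),
                               b = pmax(hits$q, hits$s),
                               pident = hits$pident)
  ed <- ed[, list(pident = max(pident)), by = c("a", "b")]
  both <- rbind(ed, data.table::data.table(a = ed$b, b = ed$a,
                                           pident = ed$pident))
  both <- unique(both)
  structure(both, class = c("identity_table", "data.table", "data.frame"))
}
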