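# shared fixtures and independent oracle implementations

tiny_index <- function() {
  protein_index(list(a = c("a.p1", "a.p2", "a.p3"),
                     b = c("b.p1", "b.p2")))
}

write_edges <- function(rows, path = tempfile(fileext = ".tsv"),
                        channel = "experimental") {
  header <- paste("protein1", "protein2", channel, sep = "\t")
  writeLines(c(header, vapply(rows, function(r) {
    paste(r, collapse = "\t")
  }, character(1))), path)
  path
}

write_blast_rows <- function(rows, path = tempfile(fileext = ".tsv")) {
  # rows: list of c(query, subject, pident, evalue)
  lines <- vapply(rows, function(r) {
    paste(c(r[1], r[2], r[3], 100, 0, 0, 1, 100, 1, 100, r[4], 200),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  path
}

write_annotation_rows <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- paste("protein", "go_term", "branch", "evidence_code", sep = "\t")
  writeLines(c(header, vapply(rows, paste, character(1), collapse = "\t")),
             path)
  path
}

# direct linear-solve oracle for the IsoRank fixed point:
# vec(S) = alpha (t(Aj) (x) t(Ai)) vec(S) + (1 - alpha) vec(R)
isorank_oracle <- function(A_i, A_j, R, alpha) {
  Ai <- isofun::row_normalize(A_i)
  Aj <- isofun::row_normalize(A_j)
  ni <- nrow(Ai); nj <- nrow(Aj)
  K <- kronecker(t(Aj), t(Ai))
  vecS <- solve(diag(ni * nj) - alpha * K, (1 - alpha) * as.vector(R))
  matrix(vecS, ni, nj)
}

random_symmetric_net <- function(n, density = 0.5) {
  A <- matrix(0, n, n)
  ut <- which(upper.tri(A))
  on <- ut[stats::runif(length(ut)) < density]
  A[on] <- stats::runif(length(on))
  A + t(A)
}

# brute-force metric oracles ------------------------------------------------

aupr_brute <- function(labels, scores) {
  npos <- sum(labels)
  taus <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0
  area <- 0
  for (tau in taus) {
    pred <- scores >= tau
    tp <- sum(pred & labels == 1)
    precision <- tp / sum(pred)
    recall <- tp / npos
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

macro_aupr_brute <- function(labels, scores) {
  vals <- c()
  for (j in seq_len(ncol(labels))) {
    if (sum(labels[, j]) == 0) next
    vals <- c(vals, aupr_brute(labels[, j], scores[, j]))
  }
  mean(vals)
}

f1_top3_brute <- function(labels, scores) {
  tp <- 0; npred <- 0
  for (i in seq_len(nrow(labels))) {
    s <- scores[i, ]
    top <- integer(0)
    for (pick in 1:3) {
      best <- which(s == max(s))[1]  # lowest index among ties
      top <- c(top, best)
      s[best] <- -Inf
    }
    npred <- npred + 3
    tp <- tp + sum(labels[i, top] == 1)
  }
  sqrt((tp / npred) * (tp / sum(labels)))
}

subset_accuracy_brute <- function(labels, scores, threshold = 0.5) {
  ok <- 0
  for (i in seq_len(nrow(labels))) {
    assigned <- which(scores[i, ] >= threshold)
    truth <- which(labels[i, ] == 1)
    if (length(assigned) == length(truth) && all(assigned == truth)) {
      ok <- ok + 1
    }
  }
  ok / nrow(labels)
}

fmax_brute <- function(labels, scores, thresholds = seq(0, 1, by = 0.01)) {
  best <- 0
  for (tau in thresholds) {
    prs <- c(); rcs <- c()
    for (i in seq_len(nrow(labels))) {
      pred <- which(scores[i, ] >= tau & scores[i, ] > 0)
      truth <- which(labels[i, ] == 1)
      if (length(pred) > 0) {
        prs <- c(prs, sum(pred %in% truth) / length(pred))
      }
      if (length(truth) > 0) {
        rcs <- c(rcs, sum(truth %in% pred) / length(truth))
      }
    }
    pr <- if (length(prs) > 0) mean(prs) else 0
    rc <- if (length(rcs) > 0) mean(rcs) else 0
    f1 <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
    best <- max(best, f1)
  }
  best
}

# small deterministic fixture directory for pipeline-level tests
pipeline_fixture <- function(seed = 7, ..., dir_tag = "pf") {
  d <- file.path(tempdir(), paste0(dir_tag, "_", seed))
  if (!dir.exists(d)) {
    simulate_multispecies(sim_config(seed = seed, ...), d)
  }
  d
}

quiet_loso <- function(...) suppressWarnings(run_loso(...))
quiet_cv <- function(...) suppressWarnings(run_cv(...))
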