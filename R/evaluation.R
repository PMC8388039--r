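#' Area under the precision-recall curve for one label
#'
#' Non-interpolated step-curve estimator: predictions are ranked by score,
#' precision and recall are evaluated at every distinct score threshold,
#' and the area is the sum of precision times the recall increment. Tied
#' scores are treated as a single threshold.
#'
#' @param labels binary vector with at least one positive.
#' @param scores numeric vector of the same length.
#' @return AUPR in \[0,1\].
#' @export
aupr <- function(labels, scores) {
  labels <- as.numeric(labels)
  npos <- sum(labels)
  if (npos == 0) stop("AUPR undefined without positive labels")
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  # threshold points: last element of each tied-score run
  keep <- c(s[-length(s)] != s[-1], TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  precision <- tp / (tp + fp)
  recall <- tp / npos
  sum(diff(c(0, recall)) * precision)
}

#' Micro-averaged AUPR
#'
#' The label and prediction matrices are vectorized and a single AUPR is
#' computed over the flattened pair.
#'
#' @param labels binary matrix (or vector).
#' @param scores numeric matrix (or vector) of the same shape.
#' @return micro AUPR.
#' @export
micro_aupr <- function(labels, scores) {
  aupr(as.vector(as.matrix(labels)), as.vector(as.matrix(scores)))
}

#' Macro- and micro-averaged AUPR
#'
#' Macro: AUPR per GO term, averaged over terms with at least one positive
#' (terms without positives are excluded and counted). Micro: AUPR over
#' the flattened matrices.
#'
#' @param labels N x c binary matrix.
#' @param scores N x c score matrix.
#' @return list with `macro`, `micro`, `per_term` (named, NA for excluded
#'   terms) and `n_excluded`.
#' @export
macro_micro_aupr <- function(labels, scores) {
  labels <- as.matrix(labels); scores <- as.matrix(scores)
  stopifnot(all(dim(labels) == dim(scores)))
  if (sum(labels) == 0) stop("no positive labels in evaluation set")
  pos <- colSums(labels) > 0
  per_term <- rep(NA_real_, ncol(labels))
  names(per_term) <- colnames(labels)
  per_term[pos] <- vapply(which(pos), function(j) {
    aupr(labels[, j], scores[, j])
  }, numeric(1))
  list(macro = mean(per_term[pos]),
       micro = micro_aupr(labels, scores),
       per_term = per_term,
       n_excluded = sum(!pos))
}

#' Expected macro AUPR of a prevalence (random-ranking) classifier
#'
#' A classifier that ranks proteins at random has expected per-term AUPR
#' equal to the term's prevalence in the evaluation set; the macro average
#' over positive terms is the chance floor the model must beat.
#'
#' @param labels N x c binary matrix.
#' @return expected macro AUPR under random ranking.
#' @export
prevalence_macro_aupr <- function(labels) {
  labels <- as.matrix(labels)
  prev <- colMeans(labels)
  mean(prev[prev > 0])
}

#' Top-3 F1 (geometric mean of micro precision and recall)
#'
#' The three highest-scoring terms of every protein are called positive
#' (ties broken deterministically toward the lower term index); micro
#' precision P and recall R are computed over the binarized matrix and
#' `sqrt(P * R)` is returned. Despite the F1 name this is the geometric,
#' not harmonic, mean — the definition is kept as published.
#'
#' @param labels N x c binary matrix, c >= 3.
#' @param scores N x c score matrix.
#' @return top-3 F1 in \[0,1\].
#' @export
f1_top3 <- function(labels, scores) {
  labels <- as.matrix(labels); scores <- as.matrix(scores)
  stopifnot(ncol(labels) >= 3, all(dim(labels) == dim(scores)))
  pred <- matrix(0L, nrow(scores), ncol(scores))
  for (i in seq_len(nrow(scores))) {
    top <- order(scores[i, ], decreasing = TRUE)[1:3]  # stable: low index wins
    pred[i, top] <- 1L
  }
  tp <- sum(pred == 1 & labels == 1)
  p <- tp / sum(pred)
  r <- tp / sum(labels)
  sqrt(p * r)
}

#' Subset accuracy at a fixed threshold
#'
#' Fraction of proteins whose thresholded predicted term set equals the
#' true set exactly — every correct term assigned and no extra term.
#' Scores greater than or equal to the threshold count as assigned.
#'
#' @param labels N x c binary matrix.
#' @param scores N x c score matrix.
#' @param threshold assignment cutoff (default 0.5).
#' @return fraction in \[0,1\].
#' @export
subset_accuracy <- function(labels, scores, threshold = 0.5) {
  labels <- as.matrix(labels); scores <- as.matrix(scores)
  pred <- scores >= threshold
  mean(rowSums(pred != (labels == 1)) == 0)
}

#' Protein-centric F-max
#'
#' For each threshold tau on a regular grid, a term is predicted when its
#' score is at least tau; a score of exactly zero is never a prediction
#' (zero encodes "no prediction", as in CAFA, so the tau = 0 grid point
#' does not call the whole ontology). Precision is averaged over proteins with at
#' least one predicted term (the CAFA convention; set
#' `all_proteins = TRUE` to average over every protein instead), recall
#' over proteins with at least one true term, and
#' `F1 = 2 * pr * rc / (pr + rc)` (zero when both vanish). F-max is the
#' maximum F1 over the grid.
#'
#' @param labels N x c binary matrix.
#' @param scores N x c score matrix.
#' @param thresholds score grid (default 0, 0.01, ..., 1).
#' @param all_proteins average precision over all proteins instead of only
#'   those with predictions.
#' @return list with `fmax` and `threshold` (the argmax tau).
#' @export
fmax <- function(labels, scores, thresholds = seq(0, 1, by = 0.01),
                 all_proteins = FALSE) {
  labels <- as.matrix(labels); scores <- as.matrix(scores)
  true_pos_rows <- rowSums(labels) > 0
  n_true <- sum(true_pos_rows)
  best <- 0; best_tau <- thresholds[1]
  for (tau in thresholds) {
    pred <- scores >= tau & scores > 0
    npred <- rowSums(pred)
    tp <- rowSums(pred & labels == 1)
    has_pred <- npred > 0
    pr <- if (all_proteins) {
      mean(ifelse(has_pred, tp / pmax(npred, 1), 0))
    } else if (any(has_pred)) {
      mean(tp[has_pred] / npred[has_pred])
    } else 0
    rc <- if (n_true > 0) {
      sum((tp / pmax(rowSums(labels), 1))[true_pos_rows]) / n_true
    } else 0
    f1 <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
    if (f1 > best) {
      best <- f1
      best_tau <- tau
    }
  }
  list(fmax = best, threshold = best_tau)
}

#' All five evaluation measures in one report
#'
#' @param labels N x c binary evaluation matrix.
#' @param scores N x c score matrix.
#' @param threshold subset-accuracy cutoff.
#' @return `metric_report` list: `macro_aupr`, `micro_aupr`, `f1_top3`
#'   (NA when c < 3), `accuracy`, `fmax`, `fmax_threshold`,
#'   `per_term_aupr`, `n_proteins`, `n_terms`, `n_terms_excluded`.
#' @export
metric_report <- function(labels, scores, threshold = 0.5) {
  labels <- as.matrix(labels); scores <- as.matrix(scores)
  au <- macro_micro_aupr(labels, scores)
  fm <- fmax(labels, scores)
  structure(list(
    macro_aupr = au$macro,
    micro_aupr = au$micro,
    f1_top3 = if (ncol(labels) >= 3) f1_top3(labels, scores) else NA_real_,
    accuracy = subset_accuracy(labels, scores, threshold),
    fmax = fm$fmax,
    fmax_threshold = fm$threshold,
    per_term_aupr = au$per_term,
    n_proteins = nrow(labels),
    n_terms = ncol(labels),
    n_terms_excluded = au$n_excluded
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "metric_report (%d proteins, %d terms, %d without positives):\n",
    x$n_proteins, x$n_terms, x$n_terms_excluded))
  cat(sprintf("  macro AUPR %.4f | micro AUPR %.4f | F1(top3) %.4f\n",
              x$macro_aupr, x$micro_aupr, x$f1_top3))
  cat(sprintf("  accuracy %.4f | F-max %.4f (tau = %.2f)\n",
              x$accuracy, x$fmax, x$fmax_threshold))
  invisible(x)
}

#' Experimental evidence codes used for evaluation labels
#' @export
EVAL_EVIDENCE_CODES <- c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP",
                         "TAS", "IC")

#' Evidence-code-aware train/evaluation label split
#'
#' Training labels come from annotations of any evidence code (including
#' electronically inferred IEA); evaluation labels are restricted to the
#' experimental-style codes, as in CAFA. Both matrices share the term
#' columns selected by [filter_terms()], so evaluation positives are a
#' subset of training positives.
#'
#' @param annotations an `annotation_table`.
#' @param index a [protein_index()].
#' @param branch GO branch.
#' @param lo,hi term-frequency window (see [filter_terms()]).
#' @param eval_codes evidence codes defining evaluation labels.
#' @return list with `train` and `eval` `label_matrix` objects.
#' @export
split_train_eval <- function(annotations, index, branch,
                             lo = 0.005, hi = 0.05,
                             eval_codes = EVAL_EVIDENCE_CODES) {
  train <- filter_terms(annotations, index, branch, lo = lo, hi = hi)
  ann <- annotations[annotations$branch == branch, ]
  eval_lm <- label_matrix_from_annotations(ann, index, branch,
                                           train$term_ids,
                                           evidence = eval_codes)
  if (sum(eval_lm$matrix) == 0) {
    warning("no evaluation-code positives for branch ", branch)
  }
  list(train = train, eval = eval_lm)
}

#' Repeated cross-validation on one target species
#'
#' In each repetition a fixed fraction of the target species' retained
#' (masked-in) proteins is held out as the test set; their labels are
#' hidden from training. The model is trained on the remaining proteins of
#' all species (or a baseline variant's subset, see
#' [variant_training_set()]) with any-evidence labels, and the test
#' proteins are scored against experimental-evidence labels. Repetitions
#' differ only in the split (and model) seed, derived deterministically
#' from `seed`.
#'
#' @param S `block_similarity` (or plain N x N matrix).
#' @param labels_train,labels_eval `label_matrix` pair from
#'   [split_train_eval()].
#' @param index a [protein_index()].
#' @param species_id the species whose annotations are tested.
#' @param config a [model_config()].
#' @param variant one of `"full"`, `"subsampled"`,
#'   `"single_annotations"`, `"single_species"` (see
#'   [variant_training_set()]).
#' @param n_reps repetitions (default 5).
#' @param test_frac held-out fraction (default 0.2; must be in (0, 1)).
#' @param seed base seed for the splits.
#' @return list with `reports` (one `metric_report` per repetition),
#'   `mean` (named vector of metric means) and `splits` (test indices).
#' @export
cross_validate <- function(S, labels_train, labels_eval, index, species_id,
                           config = preset_compact(), variant = "full",
                           n_reps = 5, test_frac = 0.2, seed = 1) {
  if (test_frac >= 1 || test_frac <= 0) {
    stop("test_frac must be in (0, 1): a full test set leaves no training data")
  }
  Smat <- if (inherits(S, "block_similarity")) S$matrix else S
  blk <- species_block(index, species_id)
  candidates <- blk[labels_train$mask[blk]]
  if (length(candidates) < 2) stop("too few annotated proteins to split")
  n_test <- max(1L, round(test_frac * length(candidates)))
  reports <- list()
  splits <- list()
  rep_seed <- seed
  for (r in seq_len(n_reps)) {
    # resample with the next seed if the draw has no evaluable positives
    for (attempt in 1:100) {
      set.seed(rep_seed)
      test <- sort(sample(candidates, n_test))
      rep_seed <- rep_seed + 1L
      if (sum(labels_eval$matrix[test, , drop = FALSE]) > 0) break
      warning("test split without evaluation positives; resampling")
    }
    train_global <- setdiff(which(labels_train$mask), test)
    vt <- variant_training_set(variant, Smat, labels_train, index,
                               species_id = species_id,
                               train_global = train_global,
                               seed = rep_seed)
    cfg <- config
    cfg$seed <- rep_seed
    model <- train_maxout(cfg, vt$features, vt$labels)
    test_features <- Smat[test, vt$feature_cols, drop = FALSE]
    scores <- predict(model, test_features)
    reports[[r]] <- metric_report(labels_eval$matrix[test, , drop = FALSE],
                                  scores)
    splits[[r]] <- test
  }
  keys <- c("macro_aupr", "micro_aupr", "f1_top3", "accuracy", "fmax")
  means <- vapply(keys, function(k) {
    mean(vapply(reports, function(rp) rp[[k]], numeric(1)))
  }, numeric(1))
  list(reports = reports, mean = means, splits = splits)
}
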