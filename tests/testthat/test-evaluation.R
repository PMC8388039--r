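test_that("aupr reproduces hand-worked two-point PR curves", {
  expect_equal(aupr(c(1, 0), c(0.9, 0.1)), 1.0)
  expect_equal(aupr(c(1, 0), c(0.1, 0.9)), 0.5)
  expect_equal(aupr(c(1, 1, 0, 0), c(0.9, 0.8, 0.7, 0.1)), 1.0)
  expect_error(aupr(c(0, 0), c(0.5, 0.6)), "positive")
})

test_that("macro averages per-term AUPRs over positive terms only", {
  labels <- cbind(c(1, 0), c(1, 0))
  scores <- cbind(c(0.9, 0.1), c(0.1, 0.9))  # one perfect, one anti-ranked
  au <- macro_micro_aupr(labels, scores)
  expect_equal(au$macro, (1.0 + 0.5) / 2)
  labels2 <- cbind(c(1, 0), c(0, 0))
  au2 <- macro_micro_aupr(labels2, scores)
  expect_equal(au2$n_excluded, 1L)
  expect_equal(au2$macro, 1.0)
  expect_true(is.na(au2$per_term[2]))
})

test_that("perfect rankings give macro = micro = 1", {
  set.seed(41)
  labels <- matrix(rbinom(60, 1, 0.3), 20, 3)
  labels[1, ] <- 1
  scores <- labels * 0.5 + 0.4  # positives 0.9, negatives 0.4
  au <- macro_micro_aupr(labels, scores)
  expect_equal(au$macro, 1.0)
  expect_equal(au$micro, 1.0)
})

test_that("micro AUPR is invariant to joint row/column permutation", {
  set.seed(42)
  labels <- matrix(rbinom(50, 1, 0.3), 10, 5)
  labels[1, 1] <- 1
  scores <- matrix(runif(50), 10, 5)
  pr <- sample(10); pc <- sample(5)
  expect_equal(micro_aupr(labels, scores),
               micro_aupr(labels[pr, pc], scores[pr, pc]))
})

test_that("f1_top3 matches hand counts and breaks ties by term index", {
  # every protein's 3 true terms top-ranked
  labels <- rbind(c(1, 1, 1, 0, 0), c(0, 1, 1, 1, 0))
  scores <- rbind(c(.9, .8, .7, .1, .2), c(.1, .9, .8, .7, .2))
  expect_equal(f1_top3(labels, scores), 1.0)
  # single protein, 1 true term ranked 1st among its top 3
  labels1 <- rbind(c(1, 0, 0, 0))
  scores1 <- rbind(c(.9, .5, .4, .1))
  expect_equal(f1_top3(labels1, scores1), sqrt(1 / 3))
  # all-equal scores: deterministic tie-break selects terms 1, 2, 3
  labels2 <- rbind(c(0, 0, 1, 1, 0))
  scores2 <- rbind(rep(0.5, 5))
  got <- f1_top3(labels2, scores2)
  expect_equal(got, sqrt((1 / 3) * (1 / 2)))  # term 3 hit, term 4 missed
})

test_that("subset accuracy demands the exact thresholded set", {
  labels <- rbind(c(1, 0), c(0, 1))
  scores <- rbind(c(0.9, 0.1), c(0.6, 0.7))
  expect_equal(subset_accuracy(labels, scores), 0.5)
  expect_equal(subset_accuracy(labels, labels), 1.0)
  expect_equal(subset_accuracy(labels, matrix(0.4, 2, 2)), 0.0)
})

test_that("fmax reproduces the one-protein threshold sweep", {
  labels <- rbind(c(1, 0))
  scores <- rbind(c(0.8, 0.3))
  fm <- fmax(labels, scores)
  expect_equal(fm$fmax, 1.0)
  expect_true(fm$threshold > 0.3 && fm$threshold <= 0.8)
  expect_equal(fmax(labels, rbind(c(0, 0)))$fmax, 0)
})

test_that("fmax upper-bounds the F1 at any single threshold", {
  set.seed(43)
  labels <- matrix(rbinom(200, 1, 0.2), 20, 10)
  labels[1, 1] <- 1
  scores <- matrix(runif(200), 20, 10)
  fm <- fmax(labels, scores)$fmax
  for (tau in c(0.1, 0.25, 0.5, 0.75, 0.9)) {
    pred <- labels * 0 + (scores >= tau & scores > 0)
    f1_at <- {
      npred <- rowSums(pred); tp <- rowSums(pred & labels == 1)
      has <- npred > 0
      pr <- if (any(has)) mean(tp[has] / npred[has]) else 0
      tr <- rowSums(labels) > 0
      rc <- mean((tp / pmax(rowSums(labels), 1))[tr])
      if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
    }
    expect_gte(fm + 1e-12, f1_at)
  }
})

test_that("all metrics agree with brute-force oracles on random fixtures", {
  set.seed(44)
  for (trial in 1:10) {
    labels <- matrix(rbinom(500, 1, 0.2), 50, 10)
    labels[1, 1] <- 1
    scores <- matrix(runif(500), 50, 10)
    au <- macro_micro_aupr(labels, scores)
    expect_equal(au$macro, macro_aupr_brute(labels, scores),
                 tolerance = 1e-10)
    expect_equal(au$micro, aupr_brute(as.vector(labels), as.vector(scores)),
                 tolerance = 1e-10)
    expect_equal(f1_top3(labels, scores), f1_top3_brute(labels, scores),
                 tolerance = 1e-10)
    expect_equal(subset_accuracy(labels, scores),
                 subset_accuracy_brute(labels, scores), tolerance = 1e-10)
    expect_equal(fmax(labels, scores)$fmax, fmax_brute(labels, scores),
                 tolerance = 1e-10)
  }
})

test_that("evidence split: IEA trains but does not evaluate", {
  idx <- protein_index(list(s = sprintf("s.p%03d", 1:100)))
  rows <- c(
    lapply(sprintf("s.p%03d", 1:3),
           function(p) c(p, "GO:a", "MF", "IEA")),
    lapply(sprintf("s.p%03d", 4:5),
           function(p) c(p, "GO:a", "MF", "EXP")),
    lapply(sprintf("s.p%03d", 6:8),
           function(p) c(p, "GO:b", "MF", "TAS"))
  )
  ann <- suppressMessages(read_annotations(write_annotation_rows(rows), idx))
  spl <- split_train_eval(ann, idx, "MF")
  # IEA-only protein: positive in train, absent from eval
  expect_equal(spl$train$matrix["s.p001", "GO:a"], 1L)
  expect_equal(spl$eval$matrix["s.p001", "GO:a"], 0L)
  # experimental-code proteins positive in both
  expect_equal(spl$eval$matrix["s.p004", "GO:a"], 1L)
  expect_equal(spl$eval$matrix["s.p006", "GO:b"], 1L)
  # eval positives are a subset of train positives
  expect_true(all(spl$train$matrix[spl$eval$matrix == 1] == 1))
})

test_that("cross_validate rejects a full-size test fraction", {
  d <- pipeline_fixture(seed = 7, dir_tag = "cv_guard")
  ds <- load_dataset(d)
  S <- build_features(ds)
  lab <- split_train_eval(ds$annotations, ds$index, "MF")
  expect_error(cross_validate(S, lab$train, lab$eval, ds$index, "sp1",
                              test_frac = 1.0), "training data")
})

test_that("cross_validate defaults to 5 reps of 20% and is reproducible", {
  d <- pipeline_fixture(seed = 7, dir_tag = "cv_repro")
  ds <- load_dataset(d)
  S <- build_features(ds)
  lab <- split_train_eval(ds$annotations, ds$index, "MF")
  cfg <- model_config(hidden_dims = c(8), maxout_units = 2, dropout = 0,
                      batch_norm = TRUE, learning_rate = 0.1,
                      batch_size = 16, max_epochs = 3, patience = 3,
                      seed = 1)
  cv1 <- suppressWarnings(
    cross_validate(S, lab$train, lab$eval, ds$index, "sp1",
                   config = cfg, seed = 2))
  expect_length(cv1$reports, 5)
  n_cand <- sum(lab$train$mask[species_block(ds$index, "sp1")])
  expect_true(all(vapply(cv1$splits, length, integer(1)) ==
                    round(0.2 * n_cand)))
  cv2 <- suppressWarnings(
    cross_validate(S, lab$train, lab$eval, ds$index, "sp1",
                   config = cfg, seed = 2))
  expect_identical(cv1$mean, cv2$mean)
  expect_identical(cv1$splits, cv2$splits)
})
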