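test_that("protein index round-trips species/local/global coordinates", {
  idx <- tiny_index()
  expect_equal(idx$total, 5)
  expect_equal(unname(idx$global_offset["b"]), 3)
  expect_equal(global_index(idx, "b", 2), 5)
  expect_equal(resolve_proteins(idx, c("b.p1", "a.p3", "nope")),
               c(4L, 3L, NA))
  expect_equal(species_of(idx, c(1, 3, 4)), c("a", "a", "b"))
  # bijection over the whole index
  g <- unlist(lapply(idx$species_ids, function(s) global_index(idx, s)))
  expect_equal(sort(g), seq_len(idx$total))
  expect_error(protein_index(list(a = "p1", b = "p1")), "unique")
})

test_that("read_network maps the STRING integer dialect onto the index", {
  idx <- tiny_index()
  f <- write_edges(list(c("a.p1", "a.p2", 700L)))
  A <- read_network(f, "a", idx)
  expect_equal(A$matrix["a.p1", "a.p2"], 0.7)
  expect_equal(A$matrix["a.p2", "a.p1"], 0.7)
  expect_equal(sum(A$matrix != 0), 2)
  expect_equal(dim(A$matrix), c(3, 3))
})

test_that("read_network handles empty files, float scores and bad inputs", {
  idx <- tiny_index()
  empty <- write_edges(list())
  expect_equal(read_network(empty, "a", idx)$matrix,
               matrix(0, 3, 3, dimnames = list(idx$proteins_per_species$a,
                                               idx$proteins_per_species$a)))
  flt <- write_edges(list(c("b.p1", "b.p2", 0.35)))
  expect_equal(read_network(flt, "b", idx)$matrix["b.p1", "b.p2"], 0.35)
  f <- write_edges(list(c("a.p1", "a.p2", 700L)))
  expect_error(read_network(f, "a", idx, channel = "textmining"),
               "channel")
  stray <- write_edges(list(c("a.p1", "zz.p9", 500L),
                            c("a.p1", "a.p3", 900L)))
  expect_warning(A <- read_network(stray, "a", idx), "skipped")
  expect_equal(A$matrix["a.p1", "a.p3"], 0.9)
  expect_equal(sum(A$matrix != 0), 2)
})

test_that("opposite-direction duplicate edges symmetrize by maximum", {
  idx <- tiny_index()
  f <- write_edges(list(c("a.p1", "a.p2", 400L), c("a.p2", "a.p1", 600L)))
  A <- read_network(f, "a", idx)
  expect_equal(A$matrix["a.p1", "a.p2"], 0.6)
  expect_equal(A$matrix["a.p2", "a.p1"], 0.6)
})

test_that("write_network then read_network is the identity", {
  idx <- tiny_index()
  set.seed(4)
  A <- adjacency_matrix("a", {
    m <- random_symmetric_net(3, density = 0.9)
    dimnames(m) <- list(idx$proteins_per_species$a,
                        idx$proteins_per_species$a)
    m
  })
  f <- tempfile(fileext = ".tsv")
  write_network(A, f, idx)
  expect_equal(read_network(f, "a", idx)$matrix, A$matrix)
})

test_that("read_annotations deduplicates, validates branches and resolves", {
  idx <- tiny_index()
  f <- write_annotation_rows(list(
    c("a.p1", "GO:1", "MF", "EXP"),
    c("a.p1", "GO:1", "MF", "EXP"),     # exact duplicate
    c("a.p2", "GO:1", "XX", "EXP"),     # bad branch
    c("b.p1", "GO:2", "BP", "IEA"),
    c("a.p3", "GO:1", "MF", "IEA")
  ))
  expect_warning(ann <- suppressMessages(read_annotations(f, idx)),
                 "branch")
  expect_equal(nrow(ann), 3)
  # records span both species' global index ranges
  expect_setequal(species_of(idx, ann$global), c("a", "b"))
  expect_equal(sort(ann$global), c(1L, 3L, 4L))
})

test_that("read_annotations aborts on a namespace mismatch", {
  idx <- tiny_index()
  f <- write_annotation_rows(list(
    c("x.p1", "GO:1", "MF", "EXP"),
    c("x.p2", "GO:1", "MF", "EXP"),
    c("a.p1", "GO:1", "MF", "EXP")
  ))
  expect_error(suppressMessages(suppressWarnings(read_annotations(f, idx))),
               "mismatch")
})

test_that("filter_terms applies the inclusive frequency window per species", {
  # one species of 1000 proteins: 0.4% dropped, 5.0% kept, 6.0% dropped
  ids <- sprintf("s.p%04d", 1:1000)
  idx <- protein_index(list(s = ids))
  rows <- c(
    lapply(ids[1:4], function(p) c(p, "GO:rare", "MF", "EXP")),
    lapply(ids[1:50], function(p) c(p, "GO:edge", "MF", "EXP")),
    lapply(ids[1:60], function(p) c(p, "GO:common", "MF", "EXP"))
  )
  ann <- suppressMessages(read_annotations(write_annotation_rows(rows), idx))
  lm <- filter_terms(ann, idx, "MF")
  expect_equal(lm$term_ids, "GO:edge")
  expect_equal(sum(lm$matrix), 50)
  # proteins annotated only with dropped terms are masked out
  expect_true(all(which(lm$mask) <= 50))
  expect_equal(sum(lm$mask), 50)
})

test_that("a term in-window for any one species is kept globally", {
  ids_a <- sprintf("a.p%03d", 1:500)   # 0.4% here: 2/500
  ids_b <- sprintf("b.p%03d", 1:100)   # 2% here: 2/100 -> kept
  idx <- protein_index(list(a = ids_a, b = ids_b))
  rows <- c(
    lapply(ids_a[1:2], function(p) c(p, "GO:x", "MF", "EXP")),
    lapply(ids_b[1:2], function(p) c(p, "GO:x", "MF", "EXP")),
    lapply(ids_b[1:3], function(p) c(p, "GO:y", "MF", "EXP"))
  )
  ann <- suppressMessages(read_annotations(write_annotation_rows(rows), idx))
  lm <- filter_terms(ann, idx, "MF")
  expect_true("GO:x" %in% lm$term_ids)
  # positives from BOTH species appear, including the sub-window species
  expect_equal(sum(lm$matrix[, "GO:x"]), 4)
})

test_that("kept-term count is monotone in the window bounds", {
  set.seed(11)
  ids <- sprintf("s.p%03d", 1:200)
  idx <- protein_index(list(s = ids))
  rows <- list()
  for (t in 1:12) {
    k <- sample(1:30, 1)
    for (p in sample(ids, k)) {
      rows[[length(rows) + 1]] <- c(p, paste0("GO:", t), "MF", "EXP")
    }
  }
  ann <- suppressMessages(read_annotations(write_annotation_rows(rows), idx))
  n_kept <- function(lo, hi)

    tryCatch(length(filter_terms(ann, idx, "MF", lo = lo, hi = hi)$term_ids),
             error = function(e) 0L)
  his <- c(0.02, 0.05, 0.1, 0.15)
  expect_true(all(diff(vapply(his, function(h) n_kept(0.005, h),
                              integer(1))) >= 0))
  los <- c(0.001, 0.005, 0.02, 0.05)
  expect_true(all(diff(vapply(los, function(l) n_kept(l, 0.15),
                              integer(1))) <= 0))
  # every masked-in protein has at least one positive
  lm <- filter_terms(ann, idx, "MF", lo = 0.005, hi = 0.15)
  expect_true(all(rowSums(lm$matrix[lm$mask, , drop = FALSE]) >= 1))
})

test_that("the container store round-trips the index and matrices", {
  idx <- tiny_index()
  S <- matrix(rnorm(25), 5, 5)
  d <- tempfile()
  save_store(d, idx, list("block_S" = S, "isorank/a_b" = S[1:3, 4:5]))
  back <- load_store(d)
  expect_equal(back$index$proteins_per_species, idx$proteins_per_species)
  expect_equal(unname(back$datasets$block_S), unname(S))
  expect_equal(unname(back$datasets[["isorank/a_b"]]),
               unname(S[1:3, 4:5]))
})
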