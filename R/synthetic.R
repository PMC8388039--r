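#' Configuration for the multispecies fixture generator
#'
#' The generator emulates the three input dialects the pipeline consumes —
#' STRING-style weighted edge lists, BLAST tabular homology and GO
#' annotation tables — from a known ground truth. Species networks are
#' noisy copies of one ancestral planted-partition graph: function is
#' carried by network modules conserved across species, which is exactly
#' the structure the homology-plus-network diffusion is designed to
#' exploit. Homology concentrates on ortholog pairs (copies of the same
#' ancestral node); GO terms attach to modules and are shared across
#' orthologs.
#'
#' @param n_species number of species.
#' @param proteins_per_species proteome size n per species (also the
#'   ancestral proteome size).
#' @param n_modules number of functional communities in the ancestral
#'   graph.
#' @param density_within,density_between edge probabilities inside/between
#'   modules of the ancestral graph.
#' @param edge_rewire_rate per-species fraction of inherited edges rewired
#'   to random pairs (network noise).
#' @param ortholog_fraction fraction of each species' proteome inherited
#'   from the ancestor; the rest are lineage-specific proteins attached
#'   randomly.
#' @param evalue_decades range of -log10 e-values for true ortholog BLAST
#'   hits (default 50-180: strong homology).
#' @param noise_decades range of -log10 e-values for spurious hits
#'   (default 0-2: above the 1e-3 cutoff, so they are zeroed downstream).
#' @param noise_hit_rate number of spurious cross-species hits per protein.
#' @param annotation_density probability an ortholog of an annotated
#'   ancestral node inherits the annotation (lower = scarcer labels).
#' @param n_terms GO terms per branch. Term positives are tiled across
#'   each module's nodes so that, at the default, most of each proteome
#'   carries at least one kept term — mirroring real annotation coverage
#'   after frequency filtering.
#' @param branches GO branches to generate (default "MF").
#' @param iea_fraction share of annotation records tagged IEA
#'   (train-only evidence); the rest are EXP.
#' @param term_freq_window target per-species frequency window the term
#'   positives are tuned into (matches the [filter_terms()] defaults).
#' @param seed RNG seed; fixed seed gives byte-identical outputs.
#' @return `sim_config` list.
#' @export
sim_config <- function(n_species = 3, proteins_per_species = 50,
                       n_modules = 5, density_within = 0.3,
                       density_between = 0.03, edge_rewire_rate = 0.1,
                       ortholog_fraction = 0.9,
                       evalue_decades = c(50, 180),
                       noise_decades = c(0, 2), noise_hit_rate = 0.5,
                       annotation_density = 0.9, n_terms = 35,
                       branches = "MF", iea_fraction = 0.2,
                       term_freq_window = c(0.005, 0.05), seed = 1) {
  stopifnot(n_species >= 1, proteins_per_species >= n_modules,
            n_modules >= 1,
            density_within > density_between, density_between >= 0,
            edge_rewire_rate >= 0, edge_rewire_rate <= 1,
            ortholog_fraction > 0, ortholog_fraction <= 1,
            annotation_density >= 0, annotation_density <= 1,
            iea_fraction >= 0, iea_fraction <= 1, n_terms >= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a multispecies fixture with known ground truth
#'
#' Writes, under `out_dir`: `networks/<species>.tsv` (STRING integer-score
#' edge lists, `experimental` channel), `blast.tsv` (12-column BLAST
#' tabular for all species pairs including self-hits at e-value 0),
#' `annotations.tsv` (protein, go_term, branch, evidence_code),
#' `proteins.tsv` (protein, species — the index manifest) and
#' `ground_truth.json`. Percent identity is anti-correlated with the
#' e-value exponent. All randomness flows from `config$seed`.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created).
#' @return invisible list: `dir`, `config`, `ground_truth` (ortholog map,
#'   module assignment, term-module map, per-term ancestral positives).
#' @export
simulate_multispecies <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  dir.create(file.path(out_dir, "networks"), recursive = TRUE,
             showWarnings = FALSE)
  n <- config$proteins_per_species
  n_anc <- n
  module <- sample(rep(seq_len(config$n_modules), length.out = n_anc))

  # ancestral planted-partition graph
  ut <- which(upper.tri(matrix(0, n_anc, n_anc)), arr.ind = TRUE)
  same <- module[ut[, 1]] == module[ut[, 2]]
  p_edge <- ifelse(same, config$density_within, config$density_between)
  anc_edge <- ut[stats::runif(nrow(ut)) < p_edge, , drop = FALSE]

  sp_ids <- sprintf("sp%d", seq_len(config$n_species))
  n_orth <- round(config$ortholog_fraction * n)
  proteins <- list()
  anc_of <- list()   # per species: ancestral node of each protein (NA = lineage-specific)
  for (s in seq_along(sp_ids)) {
    ids <- sprintf("%s.p%03d", sp_ids[s], seq_len(n))
    orth_nodes <- sort(sample.int(n_anc, n_orth))
    anc <- c(orth_nodes, rep(NA_integer_, n - n_orth))
    proteins[[sp_ids[s]]] <- ids
    anc_of[[sp_ids[s]]] <- anc
  }
  index <- protein_index(proteins)

  # species networks: inherited ancestral edges, rewired at the noise rate;
  # lineage-specific proteins attach with two random edges each
  score_of <- function(k) round(stats::runif(k, 0.4, 0.95) * 1000)
  for (s in sp_ids) {
    anc <- anc_of[[s]]
    loc_of_anc <- match(seq_len(n_anc), anc)
    e1 <- loc_of_anc[anc_edge[, 1]]
    e2 <- loc_of_anc[anc_edge[, 2]]
    keep <- !is.na(e1) & !is.na(e2)
    ed <- cbind(e1[keep], e2[keep])
    if (config$edge_rewire_rate > 0 && nrow(ed) > 0) {
      rew <- which(stats::runif(nrow(ed)) < config$edge_rewire_rate)
      for (r in rew) {
        ed[r, ] <- sample.int(n, 2)  # random pair replaces the edge
      }
      ed <- ed[ed[, 1] != ed[, 2], , drop = FALSE]
    }
    lineage <- which(is.na(anc))
    for (l in lineage) {
      ed <- rbind(ed, cbind(l, sample(setdiff(seq_len(n), l), 2)))
    }
    ids <- proteins[[s]]
    dt <- data.table::data.table(
      protein1 = ids[ed[, 1]], protein2 = ids[ed[, 2]],
      experimental = score_of(nrow(ed))
    )
    data.table::fwrite(dt, file.path(out_dir, "networks",
                                     paste0(s, ".tsv")), sep = "\t")
  }

  # BLAST table: self-hits, ortholog hits, spurious noise hits
  blast_rows <- list()
  add_hits <- function(qids, sids, evalue, pident) {
    data.table::data.table(
      qseqid = qids, sseqid = sids, pident = round(pident, 1),
      length = 100L, mismatch = 0L, gapopen = 0L, qstart = 1L,
      qend = 100L, sstart = 1L, send = 100L, evalue = evalue,
      bitscore = round(pmax(pident, 30) * 2, 1)
    )
  }
  dec <- config$evalue_decades
  pid_of <- function(u) {
    pmin(99.9, pmax(20, 25 + 70 * u / 180 + stats::rnorm(length(u), 0, 2)))
  }
  for (a in seq_along(sp_ids)) {
    for (b in a:length(sp_ids)) {
      sa <- sp_ids[a]; sb <- sp_ids[b]
      if (a == b) {
        blast_rows[[length(blast_rows) + 1]] <-
          add_hits(proteins[[sa]], proteins[[sa]], 0, 100)
        next
      }
      shared <- intersect(anc_of[[sa]], anc_of[[sb]])
      shared <- shared[!is.na(shared)]
      qa <- proteins[[sa]][match(shared, anc_of[[sa]])]
      qb <- proteins[[sb]][match(shared, anc_of[[sb]])]
      u <- stats::runif(length(shared), dec[1], dec[2])
      blast_rows[[length(blast_rows) + 1]] <-
        add_hits(qa, qb, 10^(-u), pid_of(u))
      n_noise <- round(config$noise_hit_rate * n)
      if (n_noise > 0) {
        un <- stats::runif(n_noise, config$noise_decades[1],
                           config$noise_decades[2])
        blast_rows[[length(blast_rows) + 1]] <-
          add_hits(sample(proteins[[sa]], n_noise, replace = TRUE),
                   sample(proteins[[sb]], n_noise, replace = TRUE),
                   10^(-un), pid_of(un))
      }
    }
  }
  blast <- data.table::rbindlist(blast_rows)
  data.table::fwrite(blast, file.path(out_dir, "blast.tsv"), sep = "\t",
                     col.names = FALSE)

  # annotations: terms attach to modules; a term's positives are a small
  # fixed set of ancestral nodes sized into the frequency window
  lo_n <- max(1L, ceiling(config$term_freq_window[1] * n))
  hi_n <- max(lo_n, floor(config$term_freq_window[2] * n))
  ann_rows <- list()
  term_anc <- list()
  term_module <- integer(0)
  # per-module shuffled queues: consecutive terms of a module annotate
  # distinct nodes until the module is exhausted, spreading coverage
  queues <- lapply(seq_len(config$n_modules),
                   function(m) sample(which(module == m)))
  for (br in config$branches) {
    for (t in seq_len(config$n_terms)) {
      term <- sprintf("GO:%s%04d", br, t)
      m <- ((t - 1) %% config$n_modules) + 1
      nodes_m <- which(module == m)
      k_t <- sample(lo_n:hi_n, 1)
      k_t <- min(k_t, length(nodes_m))
      if (length(queues[[m]]) < k_t) {
        queues[[m]] <- c(queues[[m]], sample(which(module == m)))
      }
      pos <- queues[[m]][seq_len(k_t)]
      queues[[m]] <- queues[[m]][-seq_len(k_t)]
      term_anc[[term]] <- pos
      term_module[term] <- m
      for (s in sp_ids) {
        loc <- match(pos, anc_of[[s]])
        loc <- loc[!is.na(loc)]
        loc <- loc[stats::runif(length(loc)) < config$annotation_density]
        if (length(loc) == 0) next
        ev <- ifelse(stats::runif(length(loc)) < config$iea_fraction,
                     "IEA", "EXP")
        ann_rows[[length(ann_rows) + 1]] <- data.table::data.table(
          protein = proteins[[s]][loc], go_term = term, branch = br,
          evidence_code = ev)
      }
    }
  }
  ann <- data.table::rbindlist(ann_rows)
  if (nrow(ann[ann$evidence_code != "IEA", ]) == 0) {
    stop("configuration produced no evaluation-code annotations")
  }
  data.table::fwrite(ann, file.path(out_dir, "annotations.tsv"), sep = "\t")

  data.table::fwrite(
    data.table::data.table(protein = all_proteins(index),
                           species = species_of(index,
                                                seq_len(index$total))),
    file.path(out_dir, "proteins.tsv"), sep = "\t")

  ground_truth <- list(
    module = module,
    ortholog_map = lapply(anc_of, function(a) as.list(a)),
    term_module = as.list(term_module),
    term_ancestral_positives = term_anc
  )
  jsonlite::write_json(ground_truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(list(dir = out_dir, config = config,
                 ground_truth = ground_truth, index = index))
}

#' Degrade a generated fixture along one axis
#'
#' Produces a modified copy of a [simulate_multispecies()] output
#' directory. `what = "homology"` removes a fraction `level` of the true
#' (below-cutoff) cross-species BLAST hits; `"network"` rewires an extra
#' fraction of each species' edges to random pairs; `"annotations"` drops
#' a fraction of annotation records. `level = 0` copies unchanged;
#' `level = 1` on homology removes every cross-species link, so all
#' off-diagonal homology blocks are zero.
#'
#' @param fixture_dir directory written by [simulate_multispecies()].
#' @param what one of `"homology"`, `"network"`, `"annotations"`.
#' @param level fraction in \[0,1\].
#' @param out_dir destination directory.
#' @param seed RNG seed for the random removals.
#' @return invisible `out_dir`.
#' @export
degrade <- function(fixture_dir, what = c("homology", "network",
                                          "annotations"),
                    level, out_dir, seed = 1) {
  what <- match.arg(what)
  stopifnot(level >= 0, level <= 1)
  set.seed(seed)
  dir.create(file.path(out_dir, "networks"), recursive = TRUE,
             showWarnings = FALSE)
  for (f in c("blast.tsv", "annotations.tsv", "proteins.tsv",
              "ground_truth.json")) {
    file.copy(file.path(fixture_dir, f), file.path(out_dir, f),
              overwrite = TRUE)
  }
  net_files <- list.files(file.path(fixture_dir, "networks"),
                          full.names = TRUE)
  file.copy(net_files, file.path(out_dir, "networks"), overwrite = TRUE)

  species_of_id <- function(ids) sub("\\..*$", "", ids)
  if (what == "homology" && level > 0) {
    bl <- data.table::fread(file.path(fixture_dir, "blast.tsv"),
                            header = FALSE,
                            colClasses = list(character = 1:2))
    cross <- species_of_id(bl[[1]]) != species_of_id(bl[[2]])
    real <- bl[[11]] <= 1e-3
    cand <- which(cross & real)
    drop <- cand[stats::runif(length(cand)) < level]
    if (level >= 1) drop <- cand
    if (length(drop) > 0) bl <- bl[-drop, ]
    data.table::fwrite(bl, file.path(out_dir, "blast.tsv"), sep = "\t",
                       col.names = FALSE)
  } else if (what == "network" && level > 0) {
    for (f in net_files) {
      dt <- data.table::fread(f, colClasses = list(character = 1:2))
      ids <- unique(c(dt$protein1, dt$protein2))
      rew <- which(stats::runif(nrow(dt)) < level)
      for (r in rew) {
        pair <- sample(ids, 2)
        dt$protein1[r] <- pair[1]
        dt$protein2[r] <- pair[2]
      }
      data.table::fwrite(dt, file.path(out_dir, "networks", basename(f)),
                         sep = "\t")
    }
  } else if (what == "annotations" && level > 0) {
    an <- data.table::fread(file.path(fixture_dir, "annotations.tsv"),
                            colClasses = "character")
    keep <- stats::runif(nrow(an)) >= level
    data.table::fwrite(an[keep, ], file.path(out_dir, "annotations.tsv"),
                       sep = "\t")
  }
  invisible(out_dir)
}
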