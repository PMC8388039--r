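#' Load a dataset directory into pipeline objects
#'
#' Expects the layout written by [simulate_multispecies()] (and accepted
#' for real data): `proteins.tsv` (protein, species — defines the index
#' and species order), `networks/<species>.tsv` edge lists, `blast.tsv`
#' (12-column tabular) and `annotations.tsv`.
#'
#' @param dir dataset directory.
#' @param channel network score column (default `"experimental"`).
#' @param species optional subset of species to load networks for
#'   (default: all in the index). The index always covers all species.
#' @return list with `index`, `networks` (named list of
#'   `adjacency_matrix`), `hits` (`blast_hits`), `annotations`
#'   (`annotation_table`).
#' @export
load_dataset <- function(dir, channel = "experimental", species = NULL) {
  man <- data.table::fread(file.path(dir, "proteins.tsv"),
                           colClasses = "character")
  sp_ids <- unique(man$species)
  index <- protein_index(split(man$protein, factor(man$species,
                                                   levels = sp_ids)))
  load_sp <- if (is.null(species)) sp_ids else species
  networks <- list()
  for (s in load_sp) {
    networks[[s]] <- read_network(file.path(dir, "networks",
                                            paste0(s, ".tsv")),
                                  s, index, channel = channel)
  }
  hits <- read_blast(file.path(dir, "blast.tsv"), index)
  annotations <- suppressMessages(
    read_annotations(file.path(dir, "annotations.tsv"), index))
  list(index = index, networks = networks, hits = hits,
       annotations = annotations)
}

#' Compute the full block similarity matrix for a dataset
#'
#' Homology blocks for every species pair, IsoRank per pair, assembly into
#' the symmetric N x N matrix whose rows are protein features.
#'
#' @param dataset a [load_dataset()] result.
#' @param alpha IsoRank diffusion weight.
#' @param cutoff,eps homology e-value cutoff and floor (see [build_R()]).
#' @param tol,max_iter IsoRank convergence controls.
#' @return `block_similarity`.
#' @export
build_features <- function(dataset, alpha = 0.6, cutoff = 1e-3,
                           eps = 1e-180, tol = 1e-6, max_iter = 50L) {
  R_blocks <- all_R_blocks(dataset$hits, dataset$index, cutoff = cutoff,
                           eps = eps)
  S_blocks <- isorank_all_pairs(dataset$networks, R_blocks, dataset$index,
                                alpha = alpha, tol = tol,
                                max_iter = max_iter)
  assemble_block(S_blocks, dataset$index)
}

# divide each feature row by its maximum; all-zero rows stay zero
normalize_rows_max <- function(X) {
  mx <- apply(X, 1, max)
  nz <- mx > 0
  X[nz, ] <- X[nz, , drop = FALSE] / mx[nz]
  X
}

#' End-to-end cross-validation run
#'
#' Reads a dataset directory, computes the block similarity matrix, builds
#' the evidence-aware label split and runs repeated cross-validation on
#' the target species (optionally with one of the ablation variants).
#'
#' @param dir dataset directory.
#' @param species_id target species for the held-out evaluation.
#' @param branch GO branch (default "MF").
#' @param alpha IsoRank diffusion weight.
#' @param config a [model_config()].
#' @param variant training-set variant (see [variant_training_set()]).
#' @param n_reps,test_frac,seed see [cross_validate()].
#' @param lo,hi term-frequency window.
#' @return list with `cv` (the [cross_validate()] result), `manifest`
#'   (run parameters and stage timings).
#' @export
run_cv <- function(dir, species_id, branch = "MF", alpha = 0.6,
                   config = preset_compact(), variant = "full",
                   n_reps = 5, test_frac = 0.2, seed = 1,
                   lo = 0.005, hi = 0.05) {
  t0 <- proc.time()[["elapsed"]]
  dataset <- load_dataset(dir)
  S <- build_features(dataset, alpha = alpha)
  t1 <- proc.time()[["elapsed"]]
  lab <- split_train_eval(dataset$annotations, dataset$index, branch,
                          lo = lo, hi = hi)
  cv <- cross_validate(S, lab$train, lab$eval, dataset$index, species_id,
                       config = config, variant = variant, n_reps = n_reps,
                       test_frac = test_frac, seed = seed)
  t2 <- proc.time()[["elapsed"]]
  manifest <- list(
    version = as.character(utils::packageVersion("isofun")),
    dir = dir, species_id = species_id, branch = branch, alpha = alpha,
    variant = variant, n_reps = n_reps, test_frac = test_frac,
    seed = seed, model = unclass(config),
    n_proteins = dataset$index$total,
    n_terms = length(lab$train$term_ids),
    timings = list(features_s = t1 - t0, cv_s = t2 - t1)
  )
  list(cv = cv, manifest = manifest)
}

#' End-to-end leave-one-species-out run
#'
#' The left-out species' network file is never read: its edge list is
#' excluded at load time, its cross-species similarity blocks are computed
#' with the identity in place of its network, its proxy network is imputed
#' by one-mode projection, and its self-similarity block comes from
#' aligning the proxy with itself. The model trains on the remaining
#' species' proteins (any-evidence labels, full-width features including
#' the imputed columns) and is evaluated on the left-out species'
#' experimental-evidence labels.
#'
#' @param dir dataset directory.
#' @param leave_out species id whose network and annotations are withheld.
#' @param branch GO branch.
#' @param alpha IsoRank diffusion weight.
#' @param config a [model_config()].
#' @param seed model seed.
#' @param normalize_rows max-normalize each feature row (default TRUE:
#'   imputed-block magnitudes differ from measured blocks, and row scaling
#'   removes that nuisance before training).
#' @param with_blast_baseline also score the left-out proteins with the
#'   BLAST annotation-transfer baseline.
#' @param lo,hi term-frequency window.
#' @return list with `report` (`metric_report` for the model),
#'   `blast_report` (baseline, or NULL), `prevalence_macro_aupr` (chance
#'   floor), `imputed` (the `imputed_network`), `manifest`.
#' @export
run_loso <- function(dir, leave_out, branch = "MF", alpha = 0.6,
                     config = preset_compact(), seed = 1,
                     normalize_rows = TRUE, with_blast_baseline = TRUE,
                     lo = 0.005, hi = 0.05) {
  t0 <- proc.time()[["elapsed"]]
  man <- data.table::fread(file.path(dir, "proteins.tsv"),
                           colClasses = "character")
  sp_ids <- unique(man$species)
  if (!leave_out %in% sp_ids) stop("leave_out species not in dataset")
  dataset <- load_dataset(dir, species = setdiff(sp_ids, leave_out))
  ls <- loso_similarity(dataset$networks, all_R_blocks(dataset$hits,
                                                       dataset$index),
                        dataset$index, leave_out, alpha = alpha)
  S <- ls$S$matrix
  if (normalize_rows) S <- normalize_rows_max(S)
  t1 <- proc.time()[["elapsed"]]
  lab <- split_train_eval(dataset$annotations, dataset$index, branch,
                          lo = lo, hi = hi)
  test <- species_block(dataset$index, leave_out)
  test <- test[lab$train$mask[test]]
  if (sum(lab$eval$matrix[test, , drop = FALSE]) == 0) {
    stop("left-out species has no evaluation-code positives")
  }
  train <- setdiff(which(lab$train$mask),
                   species_block(dataset$index, leave_out))
  cfg <- config
  cfg$seed <- seed
  model <- train_maxout(cfg, S[train, , drop = FALSE],
                        lab$train$matrix[train, , drop = FALSE])
  scores <- predict(model, S[test, , drop = FALSE])
  y_eval <- lab$eval$matrix[test, , drop = FALSE]
  report <- metric_report(y_eval, scores)
  blast_report <- NULL
  if (with_blast_baseline) {
    idt <- identity_table(dataset$hits)
    bscores <- blast_transfer(idt, lab$train$matrix, test,
                              train_proteins = train)
    blast_report <- metric_report(y_eval, bscores)
  }
  t2 <- proc.time()[["elapsed"]]
  manifest <- list(
    version = as.character(utils::packageVersion("isofun")),
    dir = dir, leave_out = leave_out, branch = branch, alpha = alpha,
    seed = seed, model = unclass(config),
    normalize_rows = normalize_rows,
    n_proteins = dataset$index$total,
    n_test = length(test), n_terms = length(lab$train$term_ids),
    timings = list(features_s = t1 - t0, train_eval_s = t2 - t1)
  )
  list(report = report, blast_report = blast_report,
       prevalence_macro_aupr = prevalence_macro_aupr(y_eval),
       imputed = ls$imputed, manifest = manifest)
}
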