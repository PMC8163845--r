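# Configuration plumbing and the command entry points tying the modules into
# the two workflows: RT training/prediction and CSM rescoring. Each command
# writes its artifacts plus a manifest (config hash, seed, package version)
# so runs are reproducible and resumable per stage.

#' Default run configuration
#'
#' The full configuration tree consumed by the \code{cmd*()} entry points,
#' with all defaults filled in; a YAML file read by \code{readRunConfig()}
#' only needs to override what differs.
#'
#' @return Nested list of class \code{"run_config"}.
#' @export
defaultRunConfig <- function() {
  cfg <- list(
    paths = list(csm_table = NULL, targets_fasta = NULL,
                 candidates_fasta = NULL, model = NULL, out_dir = "."),
    dialect = NULL,
    fractions = list(scx = 9L, hsax = 10L),
    model = list(max_len = 40L, embedding_dim = 50L, recurrent_type = "GRU",
                 recurrent_units = 50L, use_batch_norm = TRUE,
                 combination = "add", task_set = c("RP", "SCX", "hSAX"),
                 subnet_layer_sizes = c(50L, 20L, 10L), dropout_rate = 0.1,
                 learning_rate = 3e-3, epochs = 50L, batch_size = 128L),
    cv = list(k = 3L, val_frac = 0.1, fdr_cutoff = 0.01),
    features = list(dimensions = c("RP", "SCX", "hSAX"),
                    include_search_score = FALSE),
    rescoring = list(k = 3L, fdr_cutoff = 0.01, use_smote = FALSE),
    fdr = list(level = "ppi",
               thresholds = c(csm = 0.05, peptide_pair = 0.05,
                              residue_pair = 0.05, ppi = 0.01),
               separate_link_classes = TRUE),
    entrapment = list(metric = "kr_length"),
    simulation = list(n_csms = 5000L),
    seed = 1L,
    log_level = "info"
  )
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' Reads the YAML file, overlays it on \code{defaultRunConfig()} and
#' validates the schema before any work starts.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @return Validated \code{"run_config"} list.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- defaultRunConfig()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      stop("unknown config section(s): ", paste(unknown, collapse = ", "))
    }
    cfg <- utils::modifyList(cfg, user)
    class(cfg) <- "run_config"
  }
  stopifnot(cfg$cv$k >= 2L, cfg$rescoring$k >= 2L,
            cfg$fractions$scx >= 2L, cfg$fractions$hsax >= 2L)
  cfg
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

.write_manifest <- function(config, out_dir, stage) {
  manifest <- list(
    stage = stage,
    config_hash = .config_hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("xlinkRT")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

.prepare_out_dir <- function(config) {
  out_dir <- config$paths$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out_dir
}

.read_input_csms <- function(config) {
  path <- config$paths$csm_table
  if (is.null(path) || !file.exists(path)) {
    stop("config error: paths$csm_table missing or not found")
  }
  readCsmTable(path, dialect = config$dialect,
               nScx = config$fractions$scx, nHsax = config$fractions$hsax)
}

.rt_config <- function(config) {
  args <- config$model
  args$n_fractions <- list(SCX = as.integer(config$fractions$scx),
                           hSAX = as.integer(config$fractions$hsax))
  args$seed <- config$seed
  do.call(rtModelConfig, args)
}

#' Simulate a synthetic dataset to disk
#'
#' Writes the simulated CSM table (\code{csms.tsv}), the protein database
#' (\code{proteins.fasta}) and the hidden truth table (\code{truth.csv} —
#' for evaluation only, never an input to the other commands).
#'
#' @param config A \code{"run_config"} list.
#' @return Invisibly, the output directory.
#' @export
cmdSimulate <- function(config = defaultRunConfig()) {
  out_dir <- .prepare_out_dir(config)
  sim_args <- config$simulation
  sim_args$seed <- config$seed
  sim_args$n_scx <- config$fractions$scx
  sim_args$n_hsax <- config$fractions$hsax
  sc <- do.call(simConfig, sim_args)
  proteins <- simulateProteins(sc)
  sim <- simulateCsms(proteins, defaultRetentionModel(), sc)
  writeCsmTable(sim$csms, file.path(out_dir, "csms.tsv"))
  writeFastaFile(stats::setNames(proteins$sequence, proteins$accession),
                 file.path(out_dir, "proteins.fasta"))
  utils::write.csv(sim$truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  .write_manifest(config, out_dir, "simulate")
  invisible(out_dir)
}

#' Cross-validated RT training
#'
#' Runs the CV training on the configured CSM table and writes per-CSM
#' predictions (\code{rt_predictions.csv}), per-fold metrics
#' (\code{rt_metrics.csv}), per-fold training histories and the fold models
#' (\code{rt_models.rds}, a runtime artifact for \code{cmdPredict()} /
#' \code{cmdFeatures()}).
#'
#' @param config A \code{"run_config"} list.
#' @return Invisibly, the \code{runCv()} result.
#' @export
cmdTrain <- function(config = defaultRunConfig()) {
  out_dir <- .prepare_out_dir(config)
  csms <- .read_input_csms(config)
  cv <- runCv(csms, .rt_config(config), fdr_cutoff = config$cv$fdr_cutoff,
              k = config$cv$k, val_frac = config$cv$val_frac,
              seed = config$seed)
  utils::write.csv(cv$predictions, file.path(out_dir, "rt_predictions.csv"),
                   row.names = FALSE)
  utils::write.csv(cv$fold_metrics, file.path(out_dir, "rt_metrics.csv"),
                   row.names = FALSE)
  hist <- do.call(rbind, lapply(seq_along(cv$models), function(f) {
    h <- trainingHistory(cv$models[[f]])
    h$fold <- f
    h
  }))
  utils::write.csv(hist, file.path(out_dir, "rt_history.csv"),
                   row.names = FALSE)
  writeAlphabet(modelAlphabet(cv$models[[1]]),
                file.path(out_dir, "alphabet.json"))
  saveRDS(cv, file.path(out_dir, "rt_models.rds"))
  .write_manifest(config, out_dir, "train")
  invisible(cv)
}

.load_cv <- function(config, out_dir) {
  path <- config$paths$model
  if (is.null(path)) path <- file.path(out_dir, "rt_models.rds")
  if (!file.exists(path)) {
    stop("config error: no trained model at ", path, "; run cmdTrain first")
  }
  readRDS(path)
}

#' Predict retention behaviour with a trained model
#'
#' @param config A \code{"run_config"} list; uses the best fold model from
#'   the training stage.
#' @return Invisibly, the prediction data.frame
#'   (\code{predictions.csv} on disk).
#' @export
cmdPredict <- function(config = defaultRunConfig()) {
  out_dir <- .prepare_out_dir(config)
  csms <- .read_input_csms(config)
  cv <- .load_cv(config, out_dir)
  pred <- predictRt(cv$models[[cv$best_fold]], csms)
  utils::write.csv(pred, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)
  .write_manifest(config, out_dir, "predict")
  invisible(pred)
}

#' Compute the RT feature matrix
#'
#' Leak-free features from the CV fold models, written as
#' \code{features.csv} with the schema version in a header comment field.
#'
#' @param config A \code{"run_config"} list.
#' @return Invisibly, the feature matrix.
#' @export
cmdFeatures <- function(config = defaultRunConfig()) {
  out_dir <- .prepare_out_dir(config)
  csms <- .read_input_csms(config)
  cv <- .load_cv(config, out_dir)
  tri <- cvTriplets(cv, csms)
  fm <- featureMatrix(csms, tri, dimensions = config$features$dimensions,
                      include_search_score = config$features$include_search_score)
  out <- cbind(data.frame(csm_id = csmData(csms)$csm_id,
                          feature_schema = attr(fm, "feature_schema")),
               as.data.frame(fm))
  utils::write.csv(out, file.path(out_dir, "features.csv"), row.names = FALSE)
  .write_manifest(config, out_dir, "features")
  invisible(fm)
}

#' Full rescoring workflow
#'
#' Chains training, prediction, feature engineering, SVM rescoring and FDR
#' estimation: writes the rescored CSM table (\code{rescored.csv}) and the
#' FDR reports before and after rescoring.
#'
#' @param config A \code{"run_config"} list.
#' @return Invisibly, list(rescored, fdr_before, fdr_after).
#' @export
cmdRescore <- function(config = defaultRunConfig()) {
  out_dir <- .prepare_out_dir(config)
  csms <- .read_input_csms(config)
  cv <- cmdTrain(config)
  tri <- cvTriplets(cv, csms)
  fm <- featureMatrix(csms, tri, dimensions = config$features$dimensions,
                      include_search_score = config$features$include_search_score)
  rs <- rescoreCsms(csms, fm, k = config$rescoring$k,
                    fdr_cutoff = config$rescoring$fdr_cutoff,
                    use_smote = config$rescoring$use_smote,
                    seed = config$seed)
  utils::write.csv(rs, file.path(out_dir, "rescored.csv"), row.names = FALSE)
  df <- csmData(csms)
  fdr_before <- groupedFdr(df, level = config$fdr$level,
                           thresholds = config$fdr$thresholds,
                           separate_link_classes = config$fdr$separate_link_classes)
  df_re <- df
  df_re$score <- rs$xi_rescored
  fdr_after <- groupedFdr(df_re, level = config$fdr$level,
                          thresholds = config$fdr$thresholds,
                          separate_link_classes = config$fdr$separate_link_classes)
  for (lv in names(fdr_before)) {
    utils::write.csv(fdr_before[[lv]],
                     file.path(out_dir, paste0("fdr_", lv, "_before.csv")),
                     row.names = FALSE)
    utils::write.csv(fdr_after[[lv]],
                     file.path(out_dir, paste0("fdr_", lv, "_after.csv")),
                     row.names = FALSE)
  }
  .write_manifest(config, out_dir, "rescore")
  invisible(list(rescored = rs, fdr_before = fdr_before,
                 fdr_after = fdr_after))
}

#' FDR estimation for a CSM table
#'
#' @param config A \code{"run_config"} list.
#' @return Invisibly, the per-level FDR tables
#'   (written as \code{fdr_<level>.csv}).
#' @export
cmdFdr <- function(config = defaultRunConfig()) {
  out_dir <- .prepare_out_dir(config)
  csms <- .read_input_csms(config)
  res <- groupedFdr(csmData(csms), level = config$fdr$level,
                    thresholds = config$fdr$thresholds,
                    separate_link_classes = config$fdr$separate_link_classes)
  for (lv in names(res)) {
    utils::write.csv(res[[lv]], file.path(out_dir, paste0("fdr_", lv, ".csv")),
                     row.names = FALSE)
  }
  .write_manifest(config, out_dir, "fdr")
  invisible(res)
}

#' Build an entrapment database from FASTA inputs
#'
#' @param config A \code{"run_config"} list with \code{paths$targets_fasta}
#'   and \code{paths$candidates_fasta}.
#' @return Invisibly, the \code{buildEntrapmentDb()} result; writes the
#'   combined FASTA and the target-to-entrapment assignment CSV.
#' @export
cmdEntrapment <- function(config = defaultRunConfig()) {
  out_dir <- .prepare_out_dir(config)
  for (p in c("targets_fasta", "candidates_fasta")) {
    if (is.null(config$paths[[p]]) || !file.exists(config$paths[[p]])) {
      stop("config error: paths$", p, " missing or not found")
    }
  }
  targets <- readFastaFile(config$paths$targets_fasta)
  candidates <- readFastaFile(config$paths$candidates_fasta)
  res <- buildEntrapmentDb(targets, candidates,
                           metric = config$entrapment$metric)
  writeFastaFile(res$combined, file.path(out_dir, "combined_db.fasta"))
  utils::write.csv(res$assignment,
                   file.path(out_dir, "entrapment_assignment.csv"),
                   row.names = FALSE)
  .write_manifest(config, out_dir, "entrapment")
  invisible(res)
}
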