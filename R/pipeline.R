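## End-to-end pipeline: read -> score -> features -> train -> cluster ->
## fit -> test -> report.

#' Build a pipeline configuration
#'
#' All tuning parameters default to the method's published operating point:
#' K = 100 imputation neighbours, N = 3000 expected genes per cluster, 100
#' hidden units, 10 training epochs, 5% low-end truncation, q <= 0.05.
#'
#' @param maf,fis_table,features input file paths (MAF, FIS lookup TSV,
#'   static nine-covariate TSV).
#' @param output_dir directory for stage outputs (created if needed).
#' @param reference_lists optional named character vector of gene-list file
#'   paths for overlap-precision reporting.
#' @param K imputation neighbour count.
#' @param N expected genes per cluster.
#' @param hidden_units,epochs,learning_rate,batch_size network training
#'   settings.
#' @param alpha_fdr driver q-value threshold.
#' @param truncation low-end truncation fraction for the gamma fit.
#' @param bh_scope "per_cluster" or "global" BH correction.
#' @param output_activation "linear" or "relu" output unit.
#' @param seed integer seed controlling all pipeline randomness.
#' @return validated config list (class `PipelineConfig`).
#' @export
pipelineConfig <- function(maf, fis_table, features, output_dir,
                           reference_lists = NULL,
                           K = 100, N = 3000, hidden_units = 100,
                           epochs = 10, learning_rate = 0.01,
                           batch_size = 32, alpha_fdr = 0.05,
                           truncation = 0.05,
                           bh_scope = "per_cluster",
                           output_activation = "linear", seed = 1L) {
  stopifnot(K >= 1, N >= 1, hidden_units >= 1, epochs >= 1,
            alpha_fdr > 0, alpha_fdr < 1, truncation >= 0, truncation < 1,
            bh_scope %in% c("per_cluster", "global"),
            output_activation %in% c("linear", "relu"))
  structure(list(maf = maf, fis_table = fis_table, features = features,
                 output_dir = output_dir, reference_lists = reference_lists,
                 K = K, N = N, hidden_units = as.integer(hidden_units),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 alpha_fdr = alpha_fdr, truncation = truncation,
                 bh_scope = bh_scope, output_activation = output_activation,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys match the arguments of [pipelineConfig()]; unknown keys
#' are a fatal error.
#'
#' @param path YAML file path.
#' @param ... overrides applied on top of the file values.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path, ...) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  if (!is.null(vals$reference_lists))
    vals$reference_lists <- unlist(vals$reference_lists)
  do.call(pipelineConfig, vals)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("[stage %s] %s", name, conditionMessage(e)))
}

#' Run the full driver-identification pipeline
#'
#' Executes every stage, writes all stage outputs into
#' `config$output_dir`, and returns the in-memory results. The run is a
#' pure function of (input files, config, seed): repeating it produces
#' byte-identical driver lists. Outputs: `annotated_mutations.tsv`,
#' `gene_profiles.tsv`, `features_normalized.tsv`, `model.txt`,
#' `predictions.tsv`, `clusters.tsv`, `gamma_fits.tsv`,
#' `driver_calls.tsv`, `driver_genes.txt`, optional `metrics.tsv`, and
#' `manifest.yaml` recording the config and per-stage counts.
#'
#' @param config a `PipelineConfig` (or YAML path, passed through
#'   [readPipelineConfig()]).
#' @param verbose print stage-level progress messages (default TRUE).
#' @return invisibly, a list with `mutations`, `profiles`, `features`,
#'   `model`, `estimated`, `background`, `calls`, `drivers`, `metrics`,
#'   `manifest`.
#' @export
runPipeline <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "PipelineConfig"))
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  out <- config$output_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)

  for (p in c(maf = config$maf, fis_table = config$fis_table,
              features = config$features)) {
    if (!file.exists(p)) stopf("[stage input] file not found: %s", p)
  }

  muts <- stage("read_maf", readMAF(config$maf))
  say("read_maf: %d mutations (%d skipped)", nrow(muts),
      attr(muts, "skipped"))

  fisTab <- stage("fis_table", readFISTable(config$fis_table))
  ann <- stage("annotate_fis", annotateFIS(muts, fisTab))
  src <- table(factor(ann$fis_source,
                      c("lookup", "effect_mean", "fixed_fallback")))
  say("annotate_fis: lookup %d, effect_mean %d, fixed_fallback %d",
      src[1L], src[2L], src[3L])
  writeAnnotatedMutations(ann, file.path(out, "annotated_mutations.tsv"))

  profiles <- stage("gene_profiles", geneFISProfiles(ann))
  writeTSV(profiles, file.path(out, "gene_profiles.tsv"))
  say("gene_profiles: %d mutated genes", nrow(profiles))

  static <- stage("static_features", readStaticFeatures(config$features))
  fmRaw <- stage("assemble_features", assembleFeatures(static, profiles))
  nMissing <- sum(missingMask(fmRaw))
  fmImp <- stage("impute_missing", imputeMissing(fmRaw, K = config$K))
  fm <- stage("normalize", normalizeFeatures(fmImp))
  say("features: %d genes, %d cells imputed", length(geneNames(fm)),
      nMissing)
  writeFeatureMatrix(fm, file.path(out, "features_normalized.tsv"))

  targets <- stats::setNames(rep(0, length(geneNames(fm))), geneNames(fm))
  targets[profiles$gene] <- profiles$observed_fis
  model <- stage("train", trainFISModel(
    fm, targets, seed = config$seed, hiddenUnits = config$hidden_units,
    epochs = config$epochs, learningRate = config$learning_rate,
    batchSize = config$batch_size,
    outputActivation = config$output_activation))
  writeFISModel(model, file.path(out, "model.txt"))
  estimated <- stage("predict", predictFIS(model, fm))
  writeTSV(data.frame(gene = names(estimated),
                      estimated_fis = unname(estimated)),
           file.path(out, "predictions.tsv"))
  say("train/predict: final standardized MSE %.4g",
      lossTrace(model)[config$epochs])

  clusters <- stage("cluster", clusterGenes(fm, genesPerCluster = config$N))
  say("cluster: %d cluster(s), sizes %s", attr(clusters, "nClusters"),
      paste(tabulate(clusters), collapse = "/"))
  writeTSV(data.frame(gene = names(clusters), cluster = as.integer(clusters)),
           file.path(out, "clusters.tsv"))

  background <- stage("gamma_fit", estimateBackground(
    estimated, clusters, genesPerCluster = config$N,
    truncation = config$truncation))
  writeTSV(gammaFits(background), file.path(out, "gamma_fits.tsv"))
  for (i in seq_len(nrow(gammaFits(background)))) {
    f <- gammaFits(background)[i, ]
    say("  cluster %d: alpha %.3f, beta %.3f, shift %.3f, n %d",
        f$cluster, f$alpha, f$beta, f$shift, f$n_used)
  }

  calls <- stage("driver_test", callDrivers(
    profiles, background, estimated, alphaFdr = config$alpha_fdr,
    scope = config$bh_scope))
  writeDriverCalls(calls, file.path(out, "driver_calls.tsv"),
                   file.path(out, "driver_genes.txt"))
  drivers <- calls$gene[calls$is_driver]
  say("driver_test: %d driver(s) at q <= %g", length(drivers),
      config$alpha_fdr)

  metrics <- NULL
  if (length(drivers)) {
    delRatios <- deleteriousRatio(ann, drivers)
    metrics <- data.frame(
      metric = c("n_drivers", "coverage", "mean_deleterious_ratio"),
      value = c(length(drivers), patientCoverage(drivers, muts),
                mean(delRatios, na.rm = TRUE)))
    if (!is.null(config$reference_lists)) {
      for (nm in names(config$reference_lists)) {
        ref <- readGeneList(config$reference_lists[[nm]])
        metrics <- rbind(metrics, data.frame(
          metric = paste0("precision_", nm),
          value = overlapPrecision(drivers, ref)))
      }
    }
    writeTSV(metrics, file.path(out, "metrics.tsv"))
  }

  manifest <- list(
    package_version = as.character(packageVersion("finet")),
    config = unclass(config)[!vapply(unclass(config), is.null, TRUE)],
    counts = list(mutations = nrow(muts),
                  skipped_rows = attr(muts, "skipped"),
                  genes_tested = nrow(calls),
                  mutated_genes = nrow(profiles),
                  imputed_cells = nMissing,
                  clusters = as.integer(attr(clusters, "nClusters")),
                  drivers = length(drivers)))
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))

  invisible(list(mutations = muts, annotated = ann, profiles = profiles,
                 features = fm, model = model, estimated = estimated,
                 background = background, calls = calls, drivers = drivers,
                 metrics = metrics, manifest = manifest))
}
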