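# Tiny polynomial rolling hash of the deparsed config, for provenance sidecars.
.config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.write_provenance <- function(config, engine, out_dir) {
  info <- list(config_hash = .config_hash(config),
               engine = engine$name, engine_version = engine$version,
               seed = config$seed, timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(info, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Assemble a pipeline run configuration
#'
#' A single object that fully determines a pipeline run: engine, lengths,
#' sample sizes, composition, synthetic-data spec, seed and output
#' directory. All stage-level randomness is derived from `seed` through
#' named substreams.
#'
#' @param engine A [folding_engine()].
#' @param lengths Length grid (nt).
#' @param n_per_length Sequences sampled per length.
#' @param comp A [composition_spec()].
#' @param natural_fasta Optional path to a FASTA of natural sequences; when
#'   given, shape and trend studies add `natural` and `scrambled` ensembles.
#' @param synthetic A [pseudo_natural_spec()] for the classification study.
#' @param knn_k,plsda_ncomp,bootstrap_B Analysis settings.
#' @param seed Run seed.
#' @param output_dir Where artifacts are written.
#' @return A list of class `run_config`.
#' @export
run_config <- function(engine = folding_engine("vienna"),
                       lengths = c(50, 100, 200, 300, 400, 600, 800, 1000,
                                   1500, 2000, 2500, 3000),
                       n_per_length = 25L,
                       comp = composition_spec(),
                       natural_fasta = NULL,
                       synthetic = pseudo_natural_spec(),
                       knn_k = 5L, plsda_ncomp = 2L, bootstrap_B = 1000L,
                       seed = 1L,
                       output_dir = "rnamotifs_run") {
  structure(list(engine = engine, lengths = lengths,
                 n_per_length = as.integer(n_per_length), comp = comp,
                 natural_fasta = natural_fasta, synthetic = synthetic,
                 knn_k = as.integer(knn_k), plsda_ncomp = as.integer(plsda_ncomp),
                 bootstrap_B = as.integer(bootstrap_B),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Field names mirror the arguments of [run_config()]; `engine` may be
#' given as a name string, `comp` as a GC fraction, `synthetic` as a list
#' of [pseudo_natural_spec()] arguments.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$engine)) args$engine <- folding_engine(y$engine)
  if (!is.null(y$gc)) args$comp <- composition_spec(gc = y$gc)
  if (!is.null(y$synthetic)) {
    syn <- y$synthetic
    # YAML 1.1 parses a bare `n` key as logical FALSE; map it back
    names(syn)[names(syn) == "FALSE"] <- "n"
    args$synthetic <- do.call(pseudo_natural_spec, syn)
  }
  for (f in c("lengths", "n_per_length", "natural_fasta", "knn_k",
              "plsda_ncomp", "bootstrap_B", "seed", "output_dir")) {
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  }
  do.call(run_config, args)
}

.natural_ensembles <- function(config, L) {
  if (is.null(config$natural_fasta)) return(NULL)
  nat <- read_fasta(config$natural_fasta)
  nat <- filter_by_length(nat, L)
  if (nrow(nat) == 0L) return(NULL)
  scr <- scramble_sequences(nat, seed = substream_seed(config$seed, "scramble"))
  list(natural = nat, scrambled = scr)
}

#' Run the shape-frequency study
#'
#' For each configured length: sample random sequences, fold them, abstract
#' to level-5 shapes, and write the shape frequency table, the number of
#' unique shapes, and the analytic shape-space estimate. When a natural
#' FASTA is configured, natural (and scrambled) ensembles of matching
#' length are processed too, and coverage fractions plus the log–log
#' frequency correlation against the random ensemble are reported.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with per-length results (frequency tables and
#'   a one-row summary tibble each). Artifacts land in `config$output_dir`.
#' @export
run_shape_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  for (L in config$lengths) {
    seqs <- random_sequences(config$n_per_length, L, config$comp,
                             seed = substream_seed(config$seed, paste0("shape", L)))
    folded <- fold(seqs, config$engine)
    shapes <- abstract_shape(folded$db, level = 5L)
    freq <- shape_frequency_table(shapes)
    .write_tsv(freq, file.path(config$output_dir,
                               sprintf("shape_freq_random_L%d.tsv", L)))
    summary <- tibble::tibble(
      length = L, n_sampled = length(shapes), unique_shapes = nrow(freq),
      shape_space_estimate = shape_space_size(L)$estimate
    )
    nat <- .natural_ensembles(config, L)
    if (!is.null(nat)) {
      nat_folded <- fold(nat$natural, config$engine)
      nat_freq <- shape_frequency_table(abstract_shape(nat_folded$db, 5L))
      .write_tsv(nat_freq, file.path(config$output_dir,
                                     sprintf("shape_freq_natural_L%d.tsv", L)))
      summary$coverage <- coverage_fraction(nat_freq, freq)
      corr <- tryCatch(log_log_correlation(freq, nat_freq),
                       error = function(e) tibble::tibble(r = NA_real_,
                                                          p_value = NA_real_,
                                                          n_common = NA_integer_))
      summary <- dplyr::bind_cols(summary, corr)
      results[[as.character(L)]] <- list(random = freq, natural = nat_freq,
                                         summary = summary)
    } else {
      results[[as.character(L)]] <- list(random = freq, summary = summary)
    }
    jsonlite::write_json(as.list(summary),
                         file.path(config$output_dir,
                                   sprintf("shape_summary_L%d.json", L)),
                         auto_unbox = TRUE, digits = NA)
  }
  .write_provenance(config, config$engine, config$output_dir)
  invisible(results)
}

#' Run the motif-trend study
#'
#' Builds the per-structure motif-count dataset over the configured length
#' grid for the random ensemble (and natural/scrambled ensembles when a
#' FASTA is configured), fits `count = a*L + b` per motif per ensemble with
#' bootstrap confidence intervals, and writes the points (TSV) and fits
#' (JSON).
#'
#' @param config A [run_config()].
#' @return Invisibly, the `motif_trend_fit` object.
#' @export
run_trend_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  points <- build_length_grid_dataset(config$engine, config$lengths,
                                      config$n_per_length, config$comp,
                                      seed = config$seed)
  if (!is.null(config$natural_fasta)) {
    nat_all <- read_fasta(config$natural_fasta)
    for (L in config$lengths) {
      nat <- filter_by_length(nat_all, L)
      if (nrow(nat) == 0L) next
      scr <- scramble_sequences(nat, seed = substream_seed(config$seed, "scramble"))
      points <- dplyr::bind_rows(
        points,
        motif_points(fold(nat, config$engine), ensemble = "natural"),
        motif_points(fold(scr, config$engine), ensemble = "scrambled")
      )
    }
  }
  .write_tsv(points, file.path(config$output_dir, "motif_points.tsv"))
  fits <- motif_trend_fit(points, B = config$bootstrap_B, seed = config$seed)
  jsonlite::write_json(tidy.motif_trend_fit(fits),
                       file.path(config$output_dir, "motif_fits.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  .write_provenance(config, config$engine, config$output_dir)
  invisible(fits)
}

#' Run the classification study
#'
#' Generates (or ingests) a labelled two-class dataset, builds the
#' five-motif feature table, and evaluates kNN and PLS-DA under stratified
#' five-fold cross-validation, writing the feature table and both
#' classification results.
#'
#' @param config A [run_config()]; the synthetic spec defines the dataset.
#'   When a natural FASTA is configured, the positive class is the natural
#'   ensemble and the negative class its scrambled control; otherwise the
#'   synthetic pseudo-natural vs random generator is used.
#' @return Invisibly, a list with elements `knn` and `plsda`.
#' @export
run_classification_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$natural_fasta)) {
    nat <- read_fasta(config$natural_fasta)
    nat <- filter_by_length(nat, config$synthetic$L)
    scr <- scramble_sequences(nat, seed = substream_seed(config$seed, "scramble"))
    folded <- dplyr::bind_rows(
      dplyr::mutate(fold(nat, config$engine), class = "pseudo-natural"),
      dplyr::mutate(fold(scr, config$engine), class = "random")
    )
  } else {
    folded <- generate_pseudo_natural(config$synthetic, config$engine,
                                      seed = substream_seed(config$seed, "synthetic"))
  }
  feats <- make_feature_dataset(folded)
  .write_tsv(feats, file.path(config$output_dir, "features.tsv"))
  X <- feats[, setdiff(names(feats), "label")]
  cv_seed <- substream_seed(config$seed, "cv")  # shared: both methods see the same folds
  res <- list(
    knn = knn_cv(X, feats$label, k = config$knn_k, B = config$bootstrap_B,
                 seed = cv_seed),
    plsda = plsda_cv(X, feats$label, n_components = config$plsda_ncomp,
                     B = config$bootstrap_B, seed = cv_seed)
  )
  for (m in names(res)) {
    g <- glance.classification_result(res[[m]])
    jsonlite::write_json(as.list(g),
                         file.path(config$output_dir, sprintf("%s_result.json", m)),
                         auto_unbox = TRUE, digits = NA)
  }
  .write_tsv(tidy.classification_result(res$plsda),
             file.path(config$output_dir, "plsda_importances.tsv"))
  .write_provenance(config, config$engine, config$output_dir)
  invisible(res)
}
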