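#' Run configuration
#'
#' Bundles every tunable of a pipeline run: the extraction parameter
#' block, consensus settings (alpha, permutation count, minimum pattern
#' length), graph weight total, and the global seed from which
#' per-stage seeds are derived. Serialises losslessly to JSON; unknown
#' keys in a JSON config are rejected.
#'
#' @param extraction an [extraction_params] or a named list of
#'   overrides for it.
#' @param n_perm permutation replicates for the null distribution.
#' @param alpha significance level for the consensus threshold.
#' @param weight_total consensus-graph weight normalisation constant.
#' @param seed global seed; expanded deterministically into per-stage
#'   seeds.
#' @return list of class `run_config`.
#' @export
run_config <- function(extraction = extraction_params(), n_perm = 10000L,
                       alpha = 0.05, weight_total = 250, seed = 1L) {
  if (!inherits(extraction, "extraction_params"))
    extraction <- do.call(extraction_params, extraction)
  stopifnot(n_perm >= 1, alpha > 0, alpha < 1, weight_total > 0)
  structure(list(extraction = extraction, n_perm = as.integer(n_perm),
                 alpha = alpha, weight_total = weight_total,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read / write a run configuration as JSON
#' @param config a [run_config].
#' @param path JSON path.
#' @return `write_run_config`: `path` invisibly; `read_run_config`: a
#'   [run_config].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass_deep(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("extraction", "n_perm", "alpha", "weight_total", "seed")
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  ep_known <- names(formals(extraction_params))
  ep_unknown <- setdiff(names(x$extraction), ep_known)
  if (length(ep_unknown))
    stop("unknown extraction key(s): ", paste(ep_unknown, collapse = ", "))
  run_config(extraction = as.list(x$extraction),
             n_perm = x$n_perm %||% 10000L, alpha = x$alpha %||% 0.05,
             weight_total = x$weight_total %||% 250, seed = x$seed %||% 1L)
}

# Deterministic expansion of the global seed into named per-stage seeds.
stage_seeds <- function(seed, stages = c("simulate", "null", "layout")) {
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L,
                             length(stages)), stages)
}

#' Run the whole-brain tau analysis pipeline
#'
#' Executes extraction, region aggregation, ranking, consensus search,
#' permutation null and consensus-graph construction over one or more
#' samples sharing an atlas, and writes every artefact plus a manifest
#' (JSON) recording inputs, input hashes, every threshold and every
#' seed, so a run is reproducible from the manifest and inputs alone.
#' Any stage failure aborts with the stage name.
#'
#' @param volumes list of [volume3d] objects, or character paths
#'   readable by [read_volume()]; one per sample.
#' @param atlas an [atlas], or `c(label_path, region_table_path)`.
#' @param out_dir output directory (created if missing).
#' @param config a [run_config].
#' @param sample_ids sample identifiers.
#' @param pitch_override forwarded to [read_volume()] for path inputs.
#' @return list with per-sample spot tables and densities, the ranking
#'   set, consensus results, the null distribution, the consensus
#'   graph, and the manifest (also written to `manifest.json`).
#' @export
run_pipeline <- function(volumes, atlas, out_dir, config = run_config(),
                         sample_ids = NULL, pitch_override = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(volumes)
  if (is.null(sample_ids)) sample_ids <- sprintf("sample%02d", seq_len(n))
  seeds <- stage_seeds(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }
  input_files <- character(0)
  atl <- stage("aggregate", {
    if (inherits(atlas, "atlas")) atlas
    else {
      if (!all(file.exists(atlas))) stop("atlas not found")
      input_files <- c(input_files, atlas)
      read_atlas(atlas[1], atlas[2], pitch_override = pitch_override)
    }
  })
  spot_tables <- vector("list", n)
  densities <- vector("list", n)
  thresholds <- vector("list", n)
  for (i in seq_len(n)) {
    v <- volumes[[i]]
    if (is.character(v)) {
      if (!file.exists(v)) stop("stage extract: volume not found: ", v)
      input_files <- c(input_files, v)
    }
    spots <- stage("extract",
      run_extraction(v, params = config$extraction,
                     pitch_override = pitch_override,
                     sample_id = sample_ids[i]))
    write_spot_table(spots, file.path(out_dir,
                                      paste0(sample_ids[i], "_spots.csv")))
    thresholds[[i]] <- list(spot_threshold = attr(spots, "spot_threshold"),
                            n_candidate_voxels = attr(spots, "n_candidate_voxels"))
    asg <- stage("aggregate", assign_spots(spots, atl))
    densities[[i]] <- stage("aggregate", regional_density(asg, atl))
    utils::write.csv(densities[[i]],
                     file.path(out_dir, paste0(sample_ids[i], "_density.csv")),
                     row.names = FALSE)
    spot_tables[[i]] <- spots
  }
  rankings <- stage("rank", build_ranking_set(densities))
  consensus <- stage("consensus", max_consensus(rankings))
  null_dist <- stage("null",
    permutation_null(n_regions = length(rankings$region_ids),
                     k_samples = n, n_perm = config$n_perm,
                     alpha = config$alpha, seed = seeds[["null"]]))
  min_len <- if (!is.na(null_dist$threshold_length))
    min(null_dist$threshold_length, consensus$length) else consensus$length
  patterns <- stage("consensus",
    unique_patterns(rankings, min_length = min_len,
                    max_length = consensus$length))
  top <- patterns[[paste0("L", consensus$length)]]
  mean_density <- NULL
  if (!is.null(rankings$densities))
    mean_density <- stats::setNames(rowMeans(rankings$densities),
                                    rownames(rankings$densities))
  graph <- stage("graph",
    build_graph(unlist(patterns, recursive = FALSE),
                mean_density = mean_density,
                weight_total = config$weight_total))
  jsonlite::write_json(
    list(nodes = graph$nodes, edges = graph$edges,
         weight_total = graph$weight_total),
    file.path(out_dir, "graph.json"), digits = NA, auto_unbox = TRUE)
  manifest <- list(
    samples = sample_ids,
    input_hashes = as.list(tools::md5sum(input_files)),
    extraction_params = unclass(config$extraction),
    per_sample_thresholds = stats::setNames(thresholds, sample_ids),
    n_regions_ranked = length(rankings$region_ids),
    max_consensus_length = consensus$length,
    witness_sequence = consensus$sequence,
    null = list(n_perm = null_dist$n_perm, alpha = null_dist$alpha,
                seed = null_dist$seed,
                threshold_length = null_dist$threshold_length,
                p_at_threshold = if (!is.na(null_dist$threshold_length))
                  unname(null_dist$p_at[null_dist$threshold_length]) else NA),
    n_patterns = vapply(patterns, length, integer(1)),
    weight_total = config$weight_total,
    seeds = as.list(seeds),
    global_seed = config$seed)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  list(spot_tables = spot_tables, densities = densities,
       rankings = rankings, consensus = consensus, null = null_dist,
       patterns = patterns, top_sequences = top, graph = graph,
       manifest = manifest)
}
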