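# Sequential pipeline orchestration: simulate or load inputs, then fit the
# three stages in order (latent states -> deconvolution -> hazard
# contributions), freezing each stage before the next, followed by the
# standard downstream analyses. Each stage writes a checkpoint; re-running
# with the same configuration resumes from verified checkpoints.

#' Build a pipeline configuration
#'
#' @param output_dir Directory for checkpoints, tables, and the manifest.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param simulate Named list of [simulate_reference()] /
#'   [simulate_pseudobulk()] / [simulate_survival()] overrides (`n_cells`,
#'   `n_genes`, `n_clusters`, `n_batches`, `n_bulk`, `concentration`,
#'   `cells_per_sample`, `coefficients`, `coefficient_sd`, `baseline_rate`,
#'   `censor_fraction`, `split_fraction`). Used when no input paths are given.
#' @param reference,metadata,bulk,survival,spots,coordinates Optional input
#'   paths (see [read_cell_reference()], [read_bulk_matrix()],
#'   [read_survival_table()], [read_spot_data()]).
#' @param vae,deconv,hazard Named lists of stage-specific overrides passed to
#'   [fit_vae()], [fit_deconvolution()], and [fit_hazard()].
#' @param downstream Named list: `n_perm` (default 10), `top_k` (default 30).
#' @param cell_split,bulk_split Split fractions for cells and bulk samples;
#'   each must sum to 1.
#' @param ties Tie handling for the hazard stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(output_dir, seed = 1, simulate = list(),
                            reference = NULL, metadata = NULL, bulk = NULL,
                            survival = NULL, spots = NULL, coordinates = NULL,
                            vae = list(), deconv = list(), hazard = list(),
                            downstream = list(),
                            cell_split = c(0.85, 0.10, 0.05),
                            bulk_split = c(0.6, 0.2, 0.2),
                            ties = "auto") {
  if (abs(sum(cell_split) - 1) > 1e-9 || abs(sum(bulk_split) - 1) > 1e-9) {
    abort("split fractions must sum to 1.")
  }
  if (is.null(seed)) abort("a `seed` is required: every stochastic stage derives its seed from it.")
  structure(
    list(
      output_dir = output_dir, seed = as.integer(seed), simulate = simulate,
      reference = reference, metadata = metadata, bulk = bulk,
      survival = survival, spots = spots, coordinates = coordinates,
      vae = vae, deconv = deconv, hazard = hazard, downstream = downstream,
      cell_split = cell_split, bulk_split = bulk_split, ties = ties
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

config_hash <- function(config) {
  hash(config[setdiff(names(config), "output_dir")])
}

read_manifest <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (file.exists(path)) jsonlite::read_json(path) else NULL
}

# Load a checkpoint when the manifest matches the current configuration;
# verify its content hash so silent tampering between stages is caught.
load_checkpoint <- function(dir, stage, cfg_hash) {
  manifest <- read_manifest(dir)
  path <- file.path(dir, paste0(stage, ".rds"))
  if (is.null(manifest) || !file.exists(path)) {
    return(NULL)
  }
  if (!identical(manifest$config_hash, cfg_hash)) {
    return(NULL)
  }
  recorded <- manifest$checkpoints[[stage]]
  if (is.null(recorded)) {
    return(NULL)
  }
  obj <- readRDS(path)
  if (!identical(hash(obj), recorded)) {
    abort(sprintf("checkpoint '%s' does not match the manifest hash; it was modified after it was written.", stage))
  }
  inform(sprintf("stage '%s': reusing checkpoint.", stage))
  obj
}

#' Run the full sequential pipeline
#'
#' Executes, in order: input preparation (simulation or loading), the VAE
#' stage, the deconvolution stage, the hazard stage, and downstream analyses
#' (within-cluster permutation importance, gene-contribution correlations,
#' and spatial hazard mapping when spot data are present). Each fitted stage
#' is checkpointed under `output_dir` together with a JSON manifest recording
#' the configuration hash, derived seeds, checkpoint hashes, and stage
#' metrics. Re-running with an unchanged configuration resumes from the
#' checkpoints; a checkpoint whose hash no longer matches the manifest stops
#' the run.
#'
#' @param config A [pipeline_config()].
#' @param until Last stage to run: `"inputs"`, `"vae"`, `"deconv"`,
#'   `"hazard"`, or `"downstream"` (the default, i.e. everything).
#' @return Invisibly, a list with the fitted stages and downstream tables.
#' @export
run_pipeline <- function(config, until = c("downstream", "hazard", "deconv",
                                           "vae", "inputs")) {
  stopifnot(inherits(config, "pipeline_config"))
  until <- match.arg(until)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- config_hash(config)
  manifest <- read_manifest(config$output_dir)
  if (!is.null(manifest) && !identical(manifest$config_hash, cfg_hash)) {
    manifest <- NULL # configuration changed; start fresh
  }
  manifest <- manifest %||% list(
    config_hash = cfg_hash, seed = config$seed,
    checkpoints = list(), metrics = list(), stage_seeds = list()
  )
  save_manifest <- function() {
    jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  checkpoint <- function(stage, obj) {
    saveRDS(obj, file.path(config$output_dir, paste0(stage, ".rds")))
    manifest$checkpoints[[stage]] <<- hash(obj)
    save_manifest()
  }
  run_stage <- function(stage, fn) {
    obj <- tryCatch(
      load_checkpoint(config$output_dir, stage, cfg_hash) %||% fn(),
      error = function(e) {
        abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
      }
    )
    obj
  }

  # ---- inputs ----
  inputs <- run_stage("inputs", function() {
    if (is.null(config$reference)) {
      sim <- config$simulate
      arg <- function(name, default) sim[[name]] %||% default
      full <- simulate_reference(
        n_cells = arg("n_cells", 500), n_genes = arg("n_genes", 200),
        n_clusters = arg("n_clusters", 5), n_batches = arg("n_batches", 2),
        seed = derive_seed(config$seed, 11)
      )
      halves <- split_reference(full$reference,
        fraction = arg("split_fraction", 0.5),
        seed = derive_seed(config$seed, 12)
      )
      pb <- simulate_pseudobulk(halves$bulk_source,
        n_bulk = arg("n_bulk", 300),
        concentration = arg("concentration", 1),
        cells_per_sample = arg("cells_per_sample", 1000),
        seed = derive_seed(config$seed, 13)
      )
      coefficients <- sim$coefficients %||% sample_coefficient_settings(
        1, arg("n_clusters", 5),
        sd = arg("coefficient_sd", 2),
        seed = derive_seed(config$seed, 14)
      )[[1]]
      surv <- simulate_survival(pb$true_proportions, coefficients,
        baseline_rate = arg("baseline_rate", 1),
        censor_fraction = arg("censor_fraction", 0.3),
        seed = derive_seed(config$seed, 15)
      )
      list(
        reference = halves$reference, bulk = pb$counts, survival = surv,
        truth = list(
          proportions = pb$true_proportions, coefficients = coefficients
        ),
        spots = NULL
      )
    } else {
      ref <- read_cell_reference(config$reference, config$metadata)
      list(
        reference = ref,
        bulk = read_bulk_matrix(config$bulk, ref$gene),
        survival = read_survival_table(config$survival),
        truth = NULL,
        spots = if (!is.null(config$spots)) {
          read_spot_data(config$spots, config$coordinates, ref$gene)
        }
      )
    }
  })
  if (is.null(manifest$checkpoints$inputs)) checkpoint("inputs", inputs)
  if (until == "inputs") {
    return(invisible(list(inputs = inputs, manifest = manifest)))
  }

  # ---- stage 1: VAE ----
  vae <- run_stage("vae", function() {
    do.call(fit_vae, c(
      list(
        reference = inputs$reference, split = config$cell_split,
        seed = derive_seed(config$seed, 21)
      ),
      config$vae
    ))
  })
  if (is.null(manifest$checkpoints$vae)) {
    checkpoint("vae", vae)
    write_matrix_csv(vae$latent_mean, file.path(config$output_dir, "latent.csv"),
      id_name = "cell_id"
    )
  }
  manifest$metrics$vae <- list(
    best_val_elbo = vae$best_val_elbo, test_loglik = vae$test_loglik,
    epochs = nrow(vae$history)
  )
  manifest$stage_seeds$vae <- derive_seed(config$seed, 21)
  save_manifest()
  if (until == "vae") {
    return(invisible(list(inputs = inputs, vae = vae, manifest = manifest)))
  }

  # ---- stage 2: deconvolution ----
  deconv <- run_stage("deconv", function() {
    do.call(fit_deconvolution, c(
      list(bulk = inputs$bulk, vae = vae, seed = derive_seed(config$seed, 22)),
      config$deconv
    ))
  })
  if (is.null(manifest$checkpoints$deconv)) {
    checkpoint("deconv", deconv)
    write_matrix_csv(deconv$fractions, file.path(config$output_dir, "fractions.csv"),
      id_name = "cell_id"
    )
    utils::write.csv(deconv$gene_params,
      file.path(config$output_dir, "gene_params.csv"),
      row.names = FALSE
    )
  }
  manifest$metrics$deconv <- list(
    loglik = utils::tail(deconv$history$loglik, 1), iterations = nrow(deconv$history)
  )
  manifest$stage_seeds$deconv <- derive_seed(config$seed, 22)
  save_manifest()
  if (until == "deconv") {
    return(invisible(list(inputs = inputs, vae = vae, deconv = deconv, manifest = manifest)))
  }

  # ---- stage 3: hazard ----
  hazard <- run_stage("hazard", function() {
    do.call(fit_hazard, c(
      list(
        deconv = deconv, survival = inputs$survival, ties = config$ties,
        split = config$bulk_split, seed = derive_seed(config$seed, 23)
      ),
      config$hazard
    ))
  })
  if (is.null(manifest$checkpoints$hazard)) {
    checkpoint("hazard", hazard)
    utils::write.csv(tidy(hazard), file.path(config$output_dir, "contributions.csv"),
      row.names = FALSE
    )
    utils::write.csv(
      data.frame(sample_id = names(hazard$eta), eta = hazard$eta),
      file.path(config$output_dir, "eta.csv"),
      row.names = FALSE
    )
  }
  manifest$metrics$hazard <- hazard$metrics
  manifest$stage_seeds$hazard <- derive_seed(config$seed, 23)
  save_manifest()
  if (until == "hazard") {
    return(invisible(list(
      inputs = inputs, vae = vae, deconv = deconv, hazard = hazard,
      manifest = manifest
    )))
  }

  # ---- downstream ----
  downstream <- run_stage("downstream", function() {
    n_perm <- config$downstream$n_perm %||% 10
    top_k <- config$downstream$top_k %||% 30
    perm <- if (!is.null(inputs$reference$cluster)) {
      permutation_importance(
        hazard, deconv$fractions, deconv$cluster, inputs$survival,
        n_perm = n_perm, seed = derive_seed(config$seed, 24)
      )
    }
    genes <- gene_contribution_correlation(deconv$decoder_output, hazard, top_k = top_k)
    spatial <- if (!is.null(inputs$spots)) {
      spot_fit <- do.call(fit_spot_deconvolution, c(
        list(
          spots = inputs$spots, vae = vae,
          seed = derive_seed(config$seed, 25)
        ),
        config$deconv
      ))
      spatial_hazard(spot_fit, hazard)
    }
    list(permutation = perm, genes = genes, spatial = spatial)
  })
  if (is.null(manifest$checkpoints$downstream)) {
    checkpoint("downstream", downstream)
    if (!is.null(downstream$permutation)) {
      utils::write.csv(downstream$permutation,
        file.path(config$output_dir, "permutation_importance.csv"),
        row.names = FALSE
      )
    }
    utils::write.csv(downstream$genes,
      file.path(config$output_dir, "gene_correlations.csv"),
      row.names = FALSE
    )
    if (!is.null(downstream$spatial)) {
      utils::write.csv(downstream$spatial,
        file.path(config$output_dir, "spatial_hazard.csv"),
        row.names = FALSE
      )
    }
  }
  save_manifest()

  invisible(list(
    inputs = inputs, vae = vae, deconv = deconv, hazard = hazard,
    downstream = downstream, manifest = manifest
  ))
}
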