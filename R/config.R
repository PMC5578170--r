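#' Build and validate a run configuration
#'
#' A run configuration bundles every tunable of the pipeline so that a run
#' is fully determined by (config, input files, seed). Unknown fields are
#' rejected, so typos fail loudly rather than silently falling back to a
#' default.
#'
#' @param paths list with any of `fasta`, `fingerprints`, `smiles`, `edges`,
#'   `out_dir`.
#' @param wavelet list: `name` ("db4"), `levels` (4), `mode` ("symmetric"),
#'   `n_dct` (5), `dct_scope` ("all").
#' @param selection list: `enabled` (TRUE), `k` (200 or "auto"),
#'   `step_fraction` (0.1), `corr_threshold` (0.9).
#' @param svm list: `cost` (8 or "grid"), `gamma` (NULL, number, or "grid").
#' @param evaluation list: `regime` ("balanced-5fold"), `n_subsets` (10),
#'   `mask_test_net` (TRUE).
#' @param seed integer master seed.
#' @return validated `dti_config` list.
#' @export
dti_config <- function(paths = list(), wavelet = list(), selection = list(),
                       svm = list(), evaluation = list(), seed = 1L) {
  defaults <- list(
    paths = list(fasta = NULL, fingerprints = NULL, smiles = NULL,
                 edges = NULL, out_dir = "dtiwave_out"),
    wavelet = list(name = "db4", levels = 4L, mode = "symmetric",
                   n_dct = 5L, dct_scope = "all"),
    selection = list(enabled = TRUE, k = 200L, step_fraction = 0.1,
                     corr_threshold = 0.9),
    svm = list(cost = 8, gamma = NULL),
    evaluation = list(regime = "balanced-5fold", n_subsets = 10L,
                      mask_test_net = TRUE),
    seed = 1L)
  merge_block <- function(name, user) {
    base <- defaults[[name]]
    extra <- setdiff(names(user), names(base))
    if (length(extra)) {
      stop(sprintf("unknown %s field(s): %s", name,
                   paste(extra, collapse = ", ")), call. = FALSE)
    }
    base[names(user)] <- user
    base
  }
  cfg <- list(paths = merge_block("paths", paths),
              wavelet = merge_block("wavelet", wavelet),
              selection = merge_block("selection", selection),
              svm = merge_block("svm", svm),
              evaluation = merge_block("evaluation", evaluation),
              seed = as.integer(seed))
  if (!cfg$wavelet$name %in% c("haar", "db2", "db4")) {
    stop("wavelet.name must be haar, db2 or db4", call. = FALSE)
  }
  if (!cfg$evaluation$regime %in% c("balanced-5fold", "imbalanced-10fold")) {
    stop("evaluation.regime must be balanced-5fold or imbalanced-10fold",
         call. = FALSE)
  }
  structure(cfg, class = "dti_config")
}

#' Load a YAML run configuration
#'
#' @param path YAML file whose top-level blocks match the arguments of
#'   [dti_config()].
#' @return validated `dti_config`.
#' @export
read_dti_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read config files", call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  known <- c("paths", "wavelet", "selection", "svm", "evaluation", "seed")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    stop("unknown config block(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  do.call(dti_config, raw)
}

# write a manifest describing a finished run
.write_manifest <- function(dir, cfg, inputs = character(0), extra = list()) {
  manifest <- c(list(
    package_version = as.character(utils::packageVersion("dtiwave")),
    r_version = R.version.string,
    config = unclass(cfg),
    input_md5 = as.list(md5sum(inputs[file.exists(inputs)]))), extra)
  write_json(manifest, file.path(dir, "manifest.json"), auto_unbox = TRUE,
             pretty = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Run one pipeline stage from a configuration
#'
#' The programmatic core behind the command-line script
#' (`system.file("cli", "dtiwave.R", package = "dtiwave")`). Stages:
#' `"synth"` writes a synthetic benchmark into `paths$out_dir`;
#' `"featurize"` computes and writes target wavelet features and (from
#' SMILES) fingerprints; `"evaluate"` runs [evaluate_cv()] and writes the
#' report; `"rank"` writes the ranked novel-pair table. Every stage writes a
#' `manifest.json` with the config echo, seed, package version and input
#' file hashes.
#'
#' @param stage one of `"synth"`, `"featurize"`, `"evaluate"`, `"rank"`.
#' @param config a `dti_config`.
#' @return stage result, invisibly (benchmark, feature matrix, evaluation,
#'   or ranking table).
#' @export
dti_run <- function(stage = c("synth", "featurize", "evaluate", "rank"),
                    config = dti_config()) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "dti_config"))
  out_dir <- config$paths$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  need <- function(field) {
    p <- config$paths[[field]]
    if (is.null(p)) stop(sprintf("config paths.%s is required for stage '%s'",
                                 field, stage), call. = FALSE)
    if (!file.exists(p)) stop(sprintf("paths.%s does not exist: %s",
                                      field, p), call. = FALSE)
    p
  }

  if (stage == "synth") {
    bench <- synthesize_benchmark(seed = config$seed, dir = out_dir)
    .write_manifest(out_dir, config, extra = list(stage = "synth"))
    return(invisible(bench))
  }

  load_inputs <- function() {
    fasta <- need("fasta")
    edges <- need("edges")
    fp_path <- config$paths$fingerprints
    seqs <- read_protein_fasta(fasta)
    fps <- if (!is.null(fp_path)) {
      load_fingerprint_table(need("fingerprints"))
    } else {
      fingerprint_smiles_file(need("smiles"))
    }
    network <- read_edge_list(edges, drug_ids = rownames(fps),
                              target_ids = names(seqs))
    w <- config$wavelet
    tf <- featurize_targets(seqs, wavelet = w$name, levels = w$levels,
                            mode = w$mode, n_dct = w$n_dct,
                            dct_scope = w$dct_scope)
    list(network = network, target_feats = tf, fingerprints = fps,
         inputs = c(fasta, edges, fp_path %||% config$paths$smiles))
  }

  if (stage == "featurize") {
    inp <- load_inputs()
    write_feature_table(inp$target_feats,
                        file.path(out_dir, "target_features.tsv"))
    write_fingerprint_table(inp$fingerprints,
                            file.path(out_dir, "fingerprints.tsv"))
    .write_manifest(out_dir, config, inp$inputs,
                    list(stage = "featurize",
                         n_targets = nrow(inp$target_feats),
                         n_drugs = nrow(inp$fingerprints)))
    return(invisible(inp$target_feats))
  }

  if (stage == "evaluate") {
    inp <- load_inputs()
    ev <- evaluate_cv(inp$network, inp$target_feats, inp$fingerprints,
                      regime = config$evaluation$regime,
                      n_subsets = config$evaluation$n_subsets,
                      seed = config$seed,
                      selection = config$selection$enabled,
                      k = config$selection$k,
                      step_fraction = config$selection$step_fraction,
                      corr_threshold = config$selection$corr_threshold,
                      cost = config$svm$cost, gamma = config$svm$gamma,
                      mask_test_net = config$evaluation$mask_test_net)
    write_evaluation_report(ev, out_dir)
    .write_manifest(out_dir, config, inp$inputs, list(stage = "evaluate"))
    print(ev)
    return(invisible(ev))
  }

  # stage == "rank"
  inp <- load_inputs()
  top <- rank_novel_pairs(inp$network, inp$target_feats, inp$fingerprints,
                          seed = config$seed,
                          selection = config$selection$enabled,
                          k = config$selection$k,
                          step_fraction = config$selection$step_fraction,
                          corr_threshold = config$selection$corr_threshold,
                          cost = config$svm$cost, gamma = config$svm$gamma,
                          score_table_path = file.path(out_dir,
                                                       "pair_scores.tsv"))
  .write_manifest(out_dir, config, inp$inputs, list(stage = "rank"))
  invisible(top)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
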