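#' Configuration of an end-to-end pipeline run
#'
#' Bundles all module configurations, stage toggles, a single global seed
#' (fanned out deterministically to per-stage child seeds), and an output
#' directory. Serializable to YAML with [write_run_config()] /
#' [read_run_config()].
#'
#' @param seed global integer seed.
#' @param out_dir output directory for result files (`NULL`: nothing
#'   written).
#' @param stages character vector of enabled stages, a subset of
#'   `c("simulate", "behavior", "neural", "decoding", "stats")`.
#' @param task a [task_config()].
#' @param observer an [observer_config()].
#' @param neural a [neural_model_config()].
#' @param positions sample positions pooled for consistency contrasts.
#' @param n_shuffles,n_subsamples,min_trials,n_bins estimation settings for
#'   the information analyses.
#' @param use_model_estimates if `TRUE` (default when the neural stage is
#'   enabled) the behavioral analyses run on the neural model's estimates,
#'   so behavioral and neural consistency effects refer to one generative
#'   process.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = NULL,
                       stages = c("simulate", "behavior", "neural",
                                  "decoding", "stats"),
                       task = task_config(rng_seed = child_seed(seed, "task")),
                       observer = observer_config(),
                       neural = neural_model_config(
                         rng_seed = child_seed(seed, "neural")),
                       positions = c(7, 8),
                       n_shuffles = 100L, n_subsamples = 5L,
                       min_trials = 81L, n_bins = 3L,
                       use_model_estimates = "neural" %in% stages) {
  stages <- match.arg(stages, c("simulate", "behavior", "neural", "decoding",
                                "stats"), several.ok = TRUE)
  structure(list(seed = as.integer(seed), out_dir = out_dir, stages = stages,
                 task = task, observer = observer, neural = neural,
                 positions = positions, n_shuffles = as.integer(n_shuffles),
                 n_subsamples = as.integer(n_subsamples),
                 min_trials = as.integer(min_trials),
                 n_bins = as.integer(n_bins),
                 use_model_estimates = use_model_estimates),
            class = "run_config")
}

#' Serialize / restore a run configuration as YAML
#'
#' @param cfg a [run_config()].
#' @param path YAML file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` the restored `run_config` (classes reattached).
#' @export
write_run_config <- function(cfg, path) {
  plain <- rapply(unclass(cfg), unclass, how = "replace")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  v <- yaml::read_yaml(path)
  v$task <- structure(v$task, class = "task_config")
  v$observer <- structure(v$observer, class = "observer_config")
  v$neural <- structure(v$neural, class = "neural_model_config")
  structure(v, class = "run_config")
}

#' Classify the neural mechanism behind a behavioral consistency effect
#'
#' Applies the dissociation logic of the linear encoding/readout model to a
#' triplet of consistency contrasts, using each measure's *relative* drop
#' (consistent-minus-inconsistent difference divided by the consistent-side
#' value):
#'
#' * relative I(S;R) drop above `isr_threshold`: the encoding of
#'   inconsistent evidence itself is degraded - `"encoding_deficit"`;
#' * otherwise, a relative I(R;E) drop above `ire_threshold`: encoding is
#'   intact but the readout is noisier - `"decoding_noise"`;
#' * otherwise, a relative II drop above `ii_threshold`: encoding and report
#'   information are both intact while the encoded evidence fails to reach
#'   the report - `"weight_mismatch"`;
#' * otherwise `"none"`.
#'
#' The I(R;E) threshold sits higher than the others because a readout
#' rotation also produces a small I(R;E) drop through the shared encoding
#' noise; only decoding noise collapses I(R;E) outright.
#'
#' @param contrast_isr,contrast_ire,contrast_ii `consistency_contrast`s for
#'   I(S;R), I(R;E) and II(S;R;E).
#' @param isr_threshold,ire_threshold,ii_threshold relative-drop thresholds
#'   (defaults 0.25, 0.45, 0.25).
#' @return List with `mechanism` (`"encoding_deficit"`, `"decoding_noise"`,
#'   `"weight_mismatch"` or `"none"`) and the per-measure relative drops.
#' @export
classify_mechanism <- function(contrast_isr, contrast_ire, contrast_ii,
                               isr_threshold = 0.25, ire_threshold = 0.45,
                               ii_threshold = 0.25) {
  rel <- function(ct) ct$delta / max(ct$consistent$value_corrected, 1e-6)
  r_isr <- rel(contrast_isr); r_ire <- rel(contrast_ire); r_ii <- rel(contrast_ii)
  mechanism <- if (r_isr > isr_threshold) "encoding_deficit"
  else if (r_ire > ire_threshold) "decoding_noise"
  else if (r_ii > ii_threshold) "weight_mismatch"
  else "none"
  list(mechanism = mechanism,
       relative_drop = c(ISR = r_isr, IRE = r_ire, II = r_ii),
       deltas = c(ISR = contrast_isr$delta, IRE = contrast_ire$delta,
                  II = contrast_ii$delta))
}

#' Run the full simulation and analysis pipeline
#'
#' Executes the enabled stages in order - simulate (trials, cues, observer),
#' neural (encoding/readout model and tensor), behavior (psychophysical
#' kernels), decoding (cross-validated readout contrast), stats (estimate
#' distribution, psychometric fit, mechanism classification) - each seeded
#' by a child of the global seed, and optionally writes all artifacts plus a
#' provenance manifest to `cfg$out_dir`.
#'
#' @param cfg a [run_config()].
#' @return A named list bundle with the outputs of the enabled stages and a
#'   `manifest` (config hash, seeds, package version).
#' @export
run_pipeline <- function(cfg = run_config()) {
  if (!inherits(cfg, "run_config")) stop_config("cfg must be a run_config")
  bundle <- list()
  needs <- function(stage, dep) {
    if (!dep %in% cfg$stages) {
      stop_config("stage '", stage, "' requires upstream stage '", dep, "'")
    }
  }
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  if ("simulate" %in% cfg$stages) {
    trials <- generate_trials(cfg$task)
    trials <- simulate_observer(trials, cfg$observer,
                                seed = child_seed(cfg$seed, "observer"))
    bundle$trials <- trials
    if (!is.null(out_dir)) write_trials(trials, file.path(out_dir, "trials.tsv"))
  }

  if ("neural" %in% cfg$stages) {
    needs("neural", "simulate")
    sim <- simulate_neural(bundle$trials, cfg$neural,
                           positions = cfg$positions)
    bundle$tensor <- sim$tensor
    if (cfg$use_model_estimates) bundle$trials <- sim$trials
    bundle$contrasts <- lapply(
      setNames(c("ISR", "IRE", "II"), c("ISR", "IRE", "II")),
      function(m) consistency_contrast(
        bundle$tensor, bundle$trials, positions = cfg$positions, measure = m,
        n_bins = cfg$n_bins, n_shuffles = cfg$n_shuffles,
        n_subsamples = cfg$n_subsamples, min_trials = cfg$min_trials,
        seed = child_seed(cfg$seed, paste0("contrast_", m))))
    if (!is.null(out_dir)) {
      write_tensor(bundle$tensor, file.path(out_dir, "tensor"))
      ct <- do.call(rbind, lapply(bundle$contrasts, function(x) {
        data.frame(measure = x$measure, consistent = x$consistent$value_corrected,
                   inconsistent = x$inconsistent$value_corrected,
                   delta = x$delta, n_trials = x$n_trials_used)
      }))
      write.table(ct, file.path(out_dir, "neural_contrasts.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }

  if ("behavior" %in% cfg$stages) {
    needs("behavior", "simulate")
    bundle$kernel_regression <- psychophysical_kernel_regression(bundle$trials)
    bundle$kernel_mi <- psychophysical_kernel_mi(
      bundle$trials, split = "consistency", n_bins = cfg$n_bins,
      n_shuffles = cfg$n_shuffles, n_subsamples = cfg$n_subsamples,
      min_trials = cfg$min_trials,
      seed = child_seed(cfg$seed, "behavior"))
    if (!is.null(out_dir)) {
      write.table(bundle$kernel_mi, file.path(out_dir, "kernels_mi.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(bundle$kernel_regression,
                  file.path(out_dir, "kernels_regression.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if ("decoding" %in% cfg$stages) {
    needs("decoding", "neural")
    bundle$decoding <- decoding_consistency_contrast(
      bundle$tensor, bundle$trials, positions = cfg$positions,
      min_trials = cfg$min_trials, seed = child_seed(cfg$seed, "decoding"))
    if (!is.null(out_dir)) {
      dd <- data.frame(d_encoding = bundle$decoding$d_encoding,
                       d_readout = bundle$decoding$d_readout,
                       n_trials = bundle$decoding$n_trials_used)
      write.table(dd, file.path(out_dir, "decoding_contrast.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }

  if ("stats" %in% cfg$stages) {
    needs("stats", "simulate")
    bundle$estimation_stats <- estimation_distribution_stats(
      bundle$trials, n_mc = 200L, seed = child_seed(cfg$seed, "dip"))
    bundle$psychometric <- psychometric_fit(bundle$trials)
    if (!is.null(bundle$contrasts)) {
      bundle$mechanism <- classify_mechanism(bundle$contrasts$ISR,
                                             bundle$contrasts$IRE,
                                             bundle$contrasts$II)
    }
    if (!is.null(out_dir) && !is.null(bundle$mechanism)) {
      jsonlite::write_json(bundle$mechanism,
                           file.path(out_dir, "mechanism.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  bundle$manifest <- list(
    config_hash = config_hash(rapply(unclass(cfg), unclass, how = "replace")),
    seed = cfg$seed,
    child_seeds = setNames(
      lapply(c("observer", "behavior", "decoding", "dip"),
             function(s) child_seed(cfg$seed, s)),
      c("observer", "behavior", "decoding", "dip")),
    package_version = as.character(utils::packageVersion("readoutbias")))
  if (!is.null(out_dir)) {
    jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  bundle
}
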