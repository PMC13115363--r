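#' Run configuration
#'
#' Collects the optimisation hyper-parameters used across the pipeline: the
#' two modality branches are trained with Adam at `learning_rate_branch`,
#' the decision-fusion model with Adam at `learning_rate_fusion` for
#' `fusion_epochs` epochs under modality dropout with probability
#' `modality_dropout_p`.  Batch sizes follow the per-stage conventions
#' (128 face images, 32 EEG samples, 32 decision pairs).
#'
#' @param learning_rate_branch Adam learning rate for the face and EEG
#'   branches (default 5e-4).
#' @param learning_rate_fusion Adam learning rate for the fusion model
#'   (default 1e-4).
#' @param batch_face,batch_eeg,batch_fusion mini-batch sizes.
#' @param branch_epochs epochs for the modality branches (default 30).
#' @param fusion_epochs epochs for the fusion model (default 20).
#' @param modality_dropout_p probability with which a modality's decision row
#'   is suppressed during fusion training (default 0.1).
#' @param rating_threshold self-report rating above which the binary label is
#'   1 (default 5 on the 1-9 scale).
#' @param seed integer RNG seed.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(learning_rate_branch = 5e-4,
                       learning_rate_fusion = 1e-4,
                       batch_face = 128L, batch_eeg = 32L, batch_fusion = 32L,
                       branch_epochs = 30L, fusion_epochs = 20L,
                       modality_dropout_p = 0.1,
                       rating_threshold = 5,
                       seed = 1L) {
  cfg <- list(learning_rate_branch = learning_rate_branch,
              learning_rate_fusion = learning_rate_fusion,
              batch_face = as.integer(batch_face),
              batch_eeg = as.integer(batch_eeg),
              batch_fusion = as.integer(batch_fusion),
              branch_epochs = as.integer(branch_epochs),
              fusion_epochs = as.integer(fusion_epochs),
              modality_dropout_p = modality_dropout_p,
              rating_threshold = rating_threshold,
              seed = as.integer(seed))
  if (cfg$learning_rate_branch <= 0 || cfg$learning_rate_fusion <= 0)
    stop("learning rates must be positive")
  if (cfg$modality_dropout_p < 0 || cfg$modality_dropout_p > 1)
    stop("modality_dropout_p must lie in [0, 1]")
  if (any(c(cfg$batch_face, cfg$batch_eeg, cfg$batch_fusion,
            cfg$branch_epochs, cfg$fusion_epochs) < 1L))
    stop("batch sizes and epoch counts must be at least 1")
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_run_config` returns a `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param config a [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Echo a configuration into a log
#'
#' Every configuration value is written as a sorted `key = value` line so
#' that two runs with identical settings produce byte-identical logs.
#'
#' @param config a [run_config()].
#' @param file connection or path passed to [writeLines()]; use `stdout()`
#'   to print.
#' @return The log lines, invisibly.
#' @export
echo_config <- function(config, file = stdout()) {
  stopifnot(inherits(config, "run_config"))
  keys <- sort(names(config))
  lines <- vapply(keys, function(k)
    sprintf("%s = %s", k, format(config[[k]], digits = 15)), character(1))
  writeLines(lines, file)
  invisible(lines)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration\n")
  echo_config(x)
  invisible(x)
}

#' Binarize a self-report rating
#'
#' Affect ratings on the 1-9 scale are mapped to binary high/low labels:
#' 1 if the rating exceeds `threshold`, else 0 (so a rating exactly at the
#' threshold is labelled low).
#'
#' @param rating numeric vector of ratings in `[1, 9]`.
#' @param threshold decision threshold (default 5).
#' @return Integer vector of 0/1 labels.
#' @examples
#' binarize_rating(c(1, 5, 5.1, 9))  # 0 0 1 1
#' @export
binarize_rating <- function(rating, threshold = 5) {
  if (any(!is.finite(rating)) || any(rating < 1) || any(rating > 9))
    stop("ratings must lie within the [1, 9] scale")
  as.integer(rating > threshold)
}
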