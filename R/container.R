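# Versioned on-disk container for epochs, trial tables and TFDs, with
# provenance (config hash, seed, package version, step log). Arrays are
# stored via R's native serialisation, so write-then-read round-trips are
# bit-exact; metadata integrity is checked on read.

CONTAINER_VERSION <- 1L

# small stable FNV-1a hash of a serialised object (hex string)
stable_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  h <- 0x4bf29ce4                       # 31-bit FNV-1a variant
  for (b in as.integer(raw)) {
    h <- bitwXor(as.integer(h), b)
    h <- (as.numeric(h) * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Write an epoch container to disk
#'
#' Stores the epoch array with optional trial table, TFDs and generator
#' configuration, together with provenance: layout version, configuration
#' hash, seed, package version and the preprocessing log.
#'
#' @param path Destination file.
#' @param epochs An [epoch_array()].
#' @param trials Optional `trial_table`.
#' @param tfd Optional `tfd` (or named list of them).
#' @param config Optional [synth_config()] used to generate the data.
#' @return `path`, invisibly.
#' @export
write_epoch_container <- function(path, epochs, trials = NULL, tfd = NULL,
                                  config = NULL) {
  stopifnot(inherits(epochs, "epoch_array"))
  obj <- list(
    version = CONTAINER_VERSION,
    epochs = epochs, trials = trials, tfd = tfd, config = config,
    provenance = list(
      config_hash = if (!is.null(config)) stable_hash(config) else NA_character_,
      seed = if (!is.null(config)) config$seed else NA_integer_,
      package_version = as.character(utils::packageVersion("painvar")),
      log = epochs$log,
      shape = dim(epochs$data), channels = epochs$channel_names)
  )
  saveRDS(obj, path, version = 2)
  invisible(path)
}

#' Read an epoch container
#'
#' Validates the layout version and the integrity of the stored metadata
#' (declared shape and channel labels against the actual array) before
#' returning the contents.
#'
#' @param path Container file.
#' @return List with `epochs`, `trials`, `tfd`, `config`, `provenance`.
#' @export
read_epoch_container <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop(sprintf("malformed container '%s': %s", path, conditionMessage(e)),
         call. = FALSE))
  if (!is.list(obj) || is.null(obj$version))
    stop("malformed container: missing layout version", call. = FALSE)
  if (obj$version != CONTAINER_VERSION)
    stop(sprintf("unsupported container layout version %s", obj$version),
         call. = FALSE)
  pv <- obj$provenance
  if (!identical(pv$shape, dim(obj$epochs$data)) ||
      !identical(pv$channels, obj$epochs$channel_names))
    stop("container integrity error: declared shape/channels do not match data",
         call. = FALSE)
  obj
}

#' Derive a reproducible per-stage seed from a global seed
#'
#' Stages rerun in isolation see the same RNG stream as inside the full
#' pipeline: the stage seed is a stable hash of the stage name folded
#' into the global seed (always below 2^31).
#'
#' @param global_seed Integer seed.
#' @param stage Stage name.
#' @return Integer seed.
#' @export
stage_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((as.numeric(global_seed) * 7919 + h) %% .Machine$integer.max)
}
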