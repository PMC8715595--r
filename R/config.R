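# YAML run configuration: one document with per-module sections; unknown
# keys are rejected so typos never silently fall back to defaults.

run_config_defaults <- function() {
  list(
    schema_version = 1L,
    seed = 0L,
    phantom = list(grid_shape = c(64L, 64L, 16L), spacing = c(1, 1, 2),
                   n_subjects = 10L, variation_scale = 0.3),
    simulator = list(large_fraction = 0.2,
                     small_max_displacement = 5,
                     large_max_displacement = 15),
    network = list(dims = 2L, levels = 4L, base_channels = 16L,
                   dilation_rates = c(1L, 2L), dropout_p = 0.05),
    training = list(steps = 2000L, learning_rate = 1e-3, noise_sd = 0.05,
                    clip_norm = 0.3, ema_decay = 0.99, val_every = 100L,
                    alpha = 1 / 13, beta = 0.4, gamma = 0.4,
                    window_radius = 4L),
    evaluation = list(bins = 32L, n_pairs = 8L, pairing = "simulated"))
}

merge_section <- function(defaults, user, section) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown key `%s` in config section `%s`", unknown[1],
                 section))
  defaults[names(user)] <- user
  defaults
}

#' Read a run configuration
#'
#' Parses a YAML document with sections `phantom`, `simulator`, `network`,
#' `training`, `evaluation` plus top-level `seed` and `schema_version`.
#' Unknown keys are rejected; omitted keys take the documented defaults
#' (see [run_config_defaults] via `hybridreg:::run_config_defaults()`).
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return nested configuration list.
#' @export
read_run_config <- function(path = NULL) {
  def <- run_config_defaults()
  if (is.null(path)) return(def)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(def))
  if (length(unknown))
    stop(sprintf("unknown top-level config key `%s`", unknown[1]))
  out <- def
  for (k in c("schema_version", "seed"))
    if (!is.null(user[[k]])) out[[k]] <- user[[k]]
  for (k in c("phantom", "simulator", "network", "training", "evaluation"))
    out[[k]] <- merge_section(def[[k]], user[[k]], k)
  coerce_config_types(out)
}

# YAML parses whole numbers as doubles; restore the integer-typed keys
coerce_config_types <- function(cfg) {
  int_keys <- list(
    c("schema_version"), c("seed"),
    c("phantom", "grid_shape"), c("phantom", "n_subjects"),
    c("network", "dims"), c("network", "levels"),
    c("network", "base_channels"), c("network", "dilation_rates"),
    c("training", "steps"), c("training", "val_every"),
    c("training", "window_radius"),
    c("evaluation", "bins"), c("evaluation", "n_pairs"))
  for (k in int_keys) cfg[[k]] <- as.integer(cfg[[k]])
  cfg
}

#' Write a run configuration as YAML
#'
#' Round-trips through [read_run_config()] unchanged; every run directory
#' gets the effective configuration echoed for provenance.
#'
#' @param cfg configuration list.
#' @param path output YAML path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# materialize typed config objects from the plain config list
config_objects <- function(cfg) {
  tr <- cfg$training
  sim <- simulator_config(
    small = list(affine = affine_ranges(),
                 elastic = elastic_spec(
                   max_displacement = cfg$simulator$small_max_displacement)),
    large = list(affine = affine_ranges(rotation = c(-20, 20),
                                        scale = c(0.8, 1.25),
                                        translation = c(-20, 20)),
                 elastic = elastic_spec(
                   max_displacement = cfg$simulator$large_max_displacement)),
    large_fraction = cfg$simulator$large_fraction)
  list(
    phantom = phantom_spec(grid_shape = cfg$phantom$grid_shape,
                           spacing = cfg$phantom$spacing,
                           variation_scale = cfg$phantom$variation_scale),
    simulator = sim,
    network = network_spec(dims = cfg$network$dims,
                           levels = cfg$network$levels,
                           base_channels = cfg$network$base_channels,
                           dilation_rates = cfg$network$dilation_rates,
                           dropout_p = cfg$network$dropout_p),
    training = train_config(
      weights = loss_weights(tr$alpha, tr$beta, tr$gamma),
      window = similarity_window(radius = tr$window_radius),
      simulator = sim, steps = tr$steps, learning_rate = tr$learning_rate,
      noise_sd = tr$noise_sd, clip_norm = tr$clip_norm,
      ema_decay = tr$ema_decay, seed = cfg$seed,
      val_every = tr$val_every))
}
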