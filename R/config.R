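#' Load an experiment configuration
#'
#' Reads a YAML (or JSON) configuration and fills every absent field with
#' the package defaults (dt = 0.1 ms, the standard neuron constants, the
#' per-protocol learning rates). Unknown keys and invariant violations
#' raise descriptive errors. `path` may also name a packaged preset
#' (`"fig2"`, `"fig3"`, `"fig4"`, `"fig5"`, `"fig6"`).
#'
#' @param path file path or preset name.
#' @param scale optional factor in (0, 1] shrinking population sizes and
#'   repetition counts proportionally (desk-scale runs).
#' @return a validated configuration list of class `procode_config`.
#' @export
load_config <- function(path, scale = 1) {
  if (!file.exists(path)) {
    preset <- system.file("configs", paste0(path, ".yaml"),
                          package = "procode")
    if (nzchar(preset)) path <- preset
    else stop("config file not found: ", path)
  }
  raw <- yaml::read_yaml(path)
  validate_config(raw, scale = scale)
}

#' Save a configuration to YAML
#'
#' Round-trips with [load_config()].
#'
#' @param config a configuration list.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  cfg <- unclass(config)
  yaml::write_yaml(cfg, path, precision = 12L)
  invisible(path)
}

config_defaults <- function() {
  list(
    experiment = "fig2",
    dt = 0.1,
    seed = 1,
    neuron = list(C = 1, g_L = 100, g_D = 1800, E_E = 14 / 3, E_I = -1 / 3,
                  phi_max = 0.06, tau_m = 10, tau_s = 10 / 3),
    plasticity = list(alpha = 0.985, eta = 0.5, tau = 9,
                      depression_variant = "attenuated_dendritic",
                      postsynaptic_mode = "rate"),
    input = list(type = "orthogonal", n_syn = 500, rate = 0.02,
                 period = 2000),
    schedule = list(event_window = c(1800, 2000), g_E_on = 15,
                    g_I_factor = 0, p_event = 1),
    n_periods = 500,
    paired = list(n_stm = 2000, n_trials = 100, trial_len = 3000,
                  target_window = c(1500, 1700),
                  delay_window = c(1300, 1500),
                  iti_range = c(3000, 10000), n_probe = 8),
    recurrent = list(n_groups = 4, group_size = 50, pulse_ms = 100,
                     g_E_on = 20, n_repeats = 300, recall_ms = 20,
                     recall_span = 600, settle_ms = 300)
  )
}

# Recursively merge user values over defaults, rejecting unknown keys.
merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(defaults)) return(user)
  extra <- setdiff(names(user), names(defaults))
  if (length(extra))
    stop("unknown config key", if (length(extra) > 1) "s", ": ",
         paste0(path, extra, collapse = ", "))
  for (k in names(user))
    defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                  paste0(path, k, "$"))
  defaults
}

validate_config <- function(raw, scale = 1) {
  stopifnot(scale > 0, scale <= 1)
  cfg <- merge_config(config_defaults(), raw)
  np <- cfg$neuron
  # constructors enforce the invariants
  do.call(neuron_params, np)
  do.call(plasticity_params, cfg$plasticity)
  if (any(unlist(cfg$schedule[c("g_E_on", "p_event")]) < 0))
    stop("schedule amplitudes and probabilities must be non-negative")
  if (cfg$schedule$p_event > 1) stop("p_event must lie in [0, 1]")
  if (cfg$dt <= 0) stop("dt must be positive")
  if (scale < 1) {
    sc <- function(x) max(1L, as.integer(round(x * scale)))
    cfg$input$n_syn <- sc(cfg$input$n_syn)
    cfg$n_periods <- sc(cfg$n_periods)
    cfg$paired$n_stm <- sc(cfg$paired$n_stm)
    cfg$paired$n_trials <- sc(cfg$paired$n_trials)
    cfg$recurrent$group_size <- sc(cfg$recurrent$group_size)
    cfg$recurrent$n_repeats <- sc(cfg$recurrent$n_repeats)
  }
  structure(cfg, class = "procode_config")
}

# Build the constructor-level objects a runner needs from a config.
config_objects <- function(cfg) {
  list(neuron = do.call(neuron_params, cfg$neuron),
       plasticity = do.call(plasticity_params, cfg$plasticity))
}
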