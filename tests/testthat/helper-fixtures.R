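# Shared fixtures: small, fast synthetic objects built in code.

# compact recording: 25 min at 30-s frames, stimulus at 2.5 min
tiny_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, duration = 25, dt = 0.5, prestim_frames = 5L)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# small cell (few engaged pillars) so render/detect stays fast
tiny_profile <- function(name = "young", area = 350, ...) {
  p <- cohort_defaults(name)
  p$cell_area_mean <- area
  p$cell_area_sd <- 20
  p$time_to_peak <- 10
  p$time_to_peak_sd <- 1
  extra <- list(...)
  p[names(extra)] <- extra
  p
}

tiny_lattice <- function(profile = tiny_profile()) lattice_for_cohort(profile)

# deterministic noise-free variant of a config
noise_free <- function(config) {
  config$jitter_sd <- 0
  config$image_noise_sd <- 0
  config
}

# profile with all oscillation components off
still_profile <- function(p = tiny_profile()) {
  p$osc_amplitude <- 0
  p$fast_amplitude <- 0
  p
}

# hand-built force_maps object (bypasses tracking)
fake_maps <- function(ux, uy, times, k = 1, engaged = NULL) {
  np <- nrow(ux)
  structure(list(ux = ux, uy = uy, Tx = k * ux, Ty = k * uy,
                 times = times, engaged = engaged %||% rep(TRUE, np),
                 excluded = rep(FALSE, np), k = k, cell_area = NA_real_),
            class = "force_maps")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
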