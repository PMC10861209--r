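# Cohort-level drivers: simulate -> render -> detect -> force -> spectrum.

#' Simulate a cohort of cells
#'
#' Seeds the RNG from `config$seed` and generates `n_cells` independent
#' `cell_sim`s with the cohort profile (each cell draws its own area,
#' baseline force, peak increase and time-to-peak).
#'
#' @param profile A [cohort_profile()] or a cohort name accepted by
#'   [cohort_defaults()].
#' @param config A [sim_config()].
#' @param n_cells Number of cells; default `config$n_cells`.
#' @param lattice Optional shared [make_lattice()]; default sized per
#'   cohort via [lattice_for_cohort()].
#' @return List of `cell_sim` objects.
#' @export
simulate_cohort <- function(profile, config, n_cells = config$n_cells,
                            lattice = NULL) {
  if (is.character(profile)) profile <- cohort_defaults(profile)
  if (is.null(lattice)) lattice <- lattice_for_cohort(profile)
  set.seed(config$seed)
  lapply(seq_len(n_cells), function(i)
    simulate_cell_force(profile, lattice, config))
}

#' Reconstruct force maps for one simulated cell through the image pipeline
#'
#' Renders the pillar movie, detects and tracks the spots, registers the
#' rest lattice, and converts deflections to forces using the rendered cell
#' mask for the engaged set -- i.e. the same path experimental stacks take.
#'
#' @param sim A `cell_sim`.
#' @param config A [sim_config()].
#' @return A `force_maps` object.
#' @export
reconstruct_from_images <- function(sim, config = sim$config) {
  ren <- render_frames(sim, config)
  tracks <- detect_and_track(ren$frames, sim$lattice$spacing,
                             config$pixel_size, times = ren$times,
                             psf_sigma = config$psf_sigma)
  rl <- register_rest_lattice(tracks)
  deflection_to_force(tracks, rl, sim$lattice$k, mask = ren$mask,
                      mask_pixel_size = config$pixel_size)
}

#' Force metrics and instantaneous spectra for a whole cohort
#'
#' Runs the force pipeline on every simulated cell of a cohort and
#' summarizes: per-cell normalized peak, time-to-peak, baseline force and
#' cell area, plus (optionally) the per-cell instantaneous spectrum of the
#' chosen IMF.
#'
#' @param sims List of `cell_sim` (see [simulate_cohort()]).
#' @param config A [sim_config()].
#' @param from_images If TRUE (default) reconstruct through
#'   render/detect/track; if FALSE use the ground-truth deflections
#'   directly (fast path).
#' @param spectra If TRUE also compute per-cell `cell_spectrum`s.
#' @param imf_index IMF analyzed for the spectra.
#' @param max_pillars Optional per-cell cap on pillars entering the
#'   spectrum (random subsample).
#' @return A list of class `cohort_mechanics`: `cells` (data.frame peak,
#'   time_to_peak, baseline_nN, area_um2, n_engaged), `metrics` (list of
#'   `force_metrics`), `maps` (list of `force_maps`), `spectra` (list of
#'   `cell_spectrum` or NULL), `spectrum` (`cohort_spectrum` or NULL).
#' @export
cohort_mechanics <- function(sims, config, from_images = TRUE,
                             spectra = TRUE, imf_index = 2L,
                             max_pillars = NULL) {
  maps <- lapply(sims, function(s)
    if (from_images) reconstruct_from_images(s, config)
    else force_maps_from_sim(s))
  stim <- config_stim_time(config)
  mets <- lapply(maps, force_metrics, stim_time = stim)
  cells <- data.frame(
    peak = vapply(mets, `[[`, numeric(1), "peak_normalized"),
    time_to_peak = vapply(mets, `[[`, numeric(1), "time_to_peak_min"),
    baseline_nN = vapply(mets, `[[`, numeric(1), "baseline_nN"),
    area_um2 = vapply(mets, `[[`, numeric(1), "cell_area"),
    n_engaged = vapply(mets, `[[`, numeric(1), "n_engaged"))
  spl <- co <- NULL
  if (spectra) {
    spl <- lapply(maps, cell_spectrum, imf_index = imf_index,
                  max_pillars = max_pillars)
    co <- if (length(spl) >= 2) cohort_spectrum(spl) else NULL
  }
  structure(list(cells = cells, metrics = mets, maps = maps,
                 spectra = spl, spectrum = co),
            class = "cohort_mechanics")
}

#' @export
print.cohort_mechanics <- function(x, ...) {
  cat(sprintf(
    "<cohort_mechanics> n = %d cells: peak %.3f +/- %.3f, t_peak %.1f min\n",
    nrow(x$cells), mean(x$cells$peak),
    stats::sd(x$cells$peak) / sqrt(nrow(x$cells)),
    mean(x$cells$time_to_peak, na.rm = TRUE)))
  invisible(x)
}
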