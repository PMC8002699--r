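#' The packaged synthetic tracking benchmark
#'
#' Two complementary failure scenarios of a rigid box target (half-extents
#' 6 x 4 x 3 cm — an asymmetric template whose orientation is observable in
#' the depth image, subtending roughly 24 x 16 pixels) drifting smoothly at
#' about 0.5 m from the camera: an *occlusion* scenario (a nearer slab
#' covers 60% of the target for about 18% of the sequence, starting at
#' about the 36% mark) and a *displacement* scenario (an instantaneous
#' 0.151 m jump at about the 75% mark, aimed so the target stays inside
#' the frame). Both use the default depth-noise model. Each sequence is
#' 220 frames by default, so a single disturbance punctuates an otherwise
#' nominal track: most windows see ordinary tracking and lost windows are
#' the event- and configuration-driven minority.
#'
#' @param seed Base integer seed; the two scenarios use `seed` and
#'   `seed + 1`.
#' @param n_frames Frames per sequence; event placement scales with it.
#' @return Named list of two [scenario_config()]s: `occlusion`,
#'   `displacement`.
#' @export
benchmark_scenarios <- function(seed = 1L, n_frames = 220) {
  shape <- target_box(c(0.06, 0.04, 0.03))
  list(
    occlusion = scenario_config(
      n_frames = n_frames, target_shape = shape,
      occlusion_event = list(start = floor(0.36 * n_frames) + 1,
                             duration = max(1, round(0.18 * n_frames)),
                             coverage = 0.6),
      seed = seed),
    displacement = scenario_config(
      n_frames = n_frames, target_shape = shape,
      displacement_event = list(frame = max(2, round(0.75 * n_frames)),
                                translation = c(0.12, 0.07, 0.06),
                                rotation = quat(1, 0, 0, 0)),
      seed = seed + 1L)
  )
}

#' Build the benchmark window dataset
#'
#' Simulates the two benchmark scenarios, samples a stratified
#' configuration grid (particle counts capped at `k_max` to keep the
#' benchmark desk-sized), tracks every (sequence, configuration) pair and
#' windows the traces into the feature/label table.
#'
#' @param n_configs Number of filter configurations (default 60).
#' @param seed Base integer seed driving scenarios, grid and tracking.
#' @param k_max Particle-count cap for the sampled grid (default 300).
#' @param n_frames Frames per sequence (default 220, i.e. 21 windows per
#'   trace).
#' @param intr [camera_intrinsics()].
#' @param progress Print per-run progress.
#' @return Data frame as from [build_dataset()].
#' @export
benchmark_dataset <- function(n_configs = 60, seed = 1L, k_max = 300,
                              n_frames = 220, intr = camera_intrinsics(),
                              progress = FALSE) {
  scen <- benchmark_scenarios(seed = seed * 101L + 7L, n_frames = n_frames)
  sequences <- lapply(scen, simulate_sequence, intr = intr)
  grid <- sample_config_grid(n_configs, seed = seed * 103L + 11L,
                             k_max = k_max)
  build_dataset(sequences, grid, intr, seed = seed * 107L + 13L,
                progress = progress)
}
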