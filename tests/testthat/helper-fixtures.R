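# Shared fixtures: a reduced-size calibrated landscape and the season
# models at their configured (noise-free) coefficients.

small_config <- function(scale = 0.01, seed = 101L) {
  landscape_config(scale = scale, seed = seed)
}

config_season_models <- function(cfg = landscape_config()) {
  list(
    river = season_model(cfg$season$river[["intercept"]],
                         cfg$season$river[["slope"]], "river"),
    lake = season_model(cfg$season$lake[["intercept"]],
                        cfg$season$lake[["slope"]], "lake")
  )
}

# published regional aggregates used as comparison anchors in tests:
# per-component annual emissions (Pg C yr-1) and their quadrature bands
published_components <- function() {
  data.frame(
    component = c("main_channel", "rivers", "streams", "permafrost_lakes",
                  "permafrost_free_lakes", "ponds"),
    emission = c(0.004, 0.013, 0.013, 0.024, 0.008, 0.039),
    delta = c(0.001, 0.003, 0.003, 0.006, 0.002, 0.010)
  )
}
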