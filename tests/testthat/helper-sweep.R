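# The scaled-down missing-wedge sweep shared by the acceptance checks on
# comparative claims. Computed once per test run (a few minutes) and reused.

.sweep_cache <- new.env(parent = emptyenv())

acceptance_sweep <- function() {
  if (is.null(.sweep_cache$sweep)) {
    spec <- sweep_spec(max_tilts = c(45, 60, 75, 90),
                       modes = c("fixed_count", "fixed_increment"),
                       geometries = c("plane", "cylinder"), seeds = 1:3)
    .sweep_cache$spec <- spec
    .sweep_cache$sweep <- run_missing_wedge_sweep(spec)
  }
  .sweep_cache$sweep
}

acceptance_spec <- function() {
  invisible(acceptance_sweep())
  .sweep_cache$spec
}

# per-tilt medians over seeds for one condition
sweep_medians <- function(sweep, geometry, mode, metric = "fsc_avg") {
  sub <- sweep[sweep$geometry == geometry & sweep$mode == mode, ]
  med <- stats::aggregate(sub[[metric]], by = list(max_tilt = sub$max_tilt),
                          FUN = median)
  names(med)[2] <- metric
  med[order(med$max_tilt), ]
}
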