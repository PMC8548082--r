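# Declarative experiment description: beam, lens, detector, scan, sample and
# simulation models, read from YAML with documented defaults.
#
# Units at the configuration surface: energy keV, energy spread eV, voltage
# and current spread ppm, source spread mrad, flux electrons/A^2/s, defocus
# and all lengths Angstroms (underfocus positive), Cs and Cc mm, angles
# degrees. Internally angles are converted to radians at the boundary only.

#' Default simulation configuration
#'
#' Returns the full configuration with every field at its documented default:
#' a 300 keV instrument with 2.5 um underfocus, 2.7 mm spherical and
#' chromatic aberration, 0.8 eV energy spread, 0.80 ppm voltage spread,
#' 0.33 ppm current spread, 0.1 mrad source spread, 1 A pixels, 5 A
#' multislice slices and beam-damage sensitivity 0.022 A^2 per electron.
#'
#' @return A nested list of class `twin_config` with components `beam`,
#'   `lens`, `detector`, `scan`, `sample` and `simulation`.
#' @seealso [load_config()], [generate_scan()]
#' @export
default_config <- function() {
  cfg <- list(
    beam = list(
      energy = 300,          # keV
      energy_spread = 0.8,   # eV
      voltage_spread = 0.8,  # ppm, dV/V
      current_spread = 0.33, # ppm, dI/I
      source_spread = 0.1,   # mrad, illumination semi-angle
      flux = 1.0,            # e-/A^2/s
      drift = list(model = "none", amplitude = 0, period = 10, seed = 0)
    ),
    lens = list(
      defocus = 25000,            # A, underfocus positive
      spherical_aberration = 2.7, # mm
      chromatic_aberration = 2.7, # mm
      phase_plate_shift = 0       # radians
    ),
    detector = list(
      nx = 128,
      ny = 128,
      pixel_size = 1,                   # A
      dqe = list(dqe0 = 0.8, falloff = 0.6) # DQE(q) = dqe0*(1 - falloff*(q/qN)^2)
    ),
    scan = list(
      axis = c(0, 1, 0),
      max_tilt = 60,         # degrees
      mode = "fixed_count",  # or "fixed_increment"
      num_images = 61,
      increment = 2,         # degrees, used in fixed_increment mode
      exposure = 1,          # s per image
      translation = 0,       # A per image, along x
      ordering = "dose_symmetric" # or "sequential"
    ),
    sample = list(
      geometry = list(shape = "plane", x_width = 1000, y_width = 1000,
                      z_depth = 500),
      particles = list(),
      ice = list(model = "none")
    ),
    simulation = list(
      slice_thickness = 5,        # A, multislice z-slice
      pixel_size = 1,             # A, potential sampling (defaults to detector)
      damage_sensitivity = 0.022, # A^2/e-, B = 8 pi^2 D_E S_E
      mean_free_path = 3140,      # A, inelastic mean free path (Inf: no loss)
      atom_amplitude = 30,        # V*A^3 integrated projected potential per Z
      atom_sigma = 1.0,           # A, Gaussian atom half-width
      band_limit = TRUE,          # anti-alias aperture at 2/3 Nyquist
      dose_scale = 1,             # ensemble factor for counting statistics
      seed = 0
    )
  )
  class(cfg) <- "twin_config"
  cfg
}

# Recursively merge user values into the default template, rejecting unknown
# keys (with their full path) so typos fail loudly.
merge_config <- function(template, user, path = character()) {
  if (is.null(user)) return(template)
  if (!is.list(user)) {
    stop("configuration key '", paste(path, collapse = "."),
         "' must be a mapping", call. = FALSE)
  }
  unknown <- setdiff(names(user), names(template))
  if (length(unknown) > 0) {
    stop("unknown configuration key '",
         paste(c(path, unknown[1]), collapse = "."), "'", call. = FALSE)
  }
  free_subtrees <- list(c("sample", "particles"), c("sample", "geometry"),
                        c("sample", "ice"))
  for (key in names(user)) {
    # free-form subtrees validated by the sample builder, not by key name
    free <- any(vapply(free_subtrees, identical, logical(1), y = c(path, key)))
    if (is.list(template[[key]]) && !is.null(names(template[[key]])) && !free) {
      template[[key]] <- merge_config(template[[key]], user[[key]], c(path, key))
    } else {
      value <- user[[key]]
      if (is.list(value) && !free && is.null(names(value))) value <- unlist(value)
      template[[key]] <- value
    }
  }
  template
}

check_positive <- function(x, key) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    stop("configuration key '", key, "' must be a positive number", call. = FALSE)
  }
}

check_nonneg <- function(x, key) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0) {
    stop("configuration key '", key, "' must be >= 0", call. = FALSE)
  }
}

validate_config <- function(cfg) {
  check_positive(cfg$beam$energy, "beam.energy")
  check_nonneg(cfg$beam$energy_spread, "beam.energy_spread")
  check_nonneg(cfg$beam$voltage_spread, "beam.voltage_spread")
  check_nonneg(cfg$beam$current_spread, "beam.current_spread")
  check_nonneg(cfg$beam$source_spread, "beam.source_spread")
  check_positive(cfg$beam$flux, "beam.flux")
  if (!cfg$beam$drift$model %in% c("none", "random", "sinusoidal")) {
    stop("configuration key 'beam.drift.model' must be one of none, random, sinusoidal",
         call. = FALSE)
  }
  check_nonneg(cfg$lens$spherical_aberration, "lens.spherical_aberration")
  check_nonneg(cfg$lens$chromatic_aberration, "lens.chromatic_aberration")
  if (cfg$detector$nx < 1 || cfg$detector$ny < 1) {
    stop("configuration keys 'detector.nx'/'detector.ny' must be >= 1", call. = FALSE)
  }
  check_positive(cfg$detector$pixel_size, "detector.pixel_size")
  dqe0 <- cfg$detector$dqe$dqe0
  if (!is.numeric(dqe0) || dqe0 <= 0 || dqe0 > 1) {
    stop("configuration key 'detector.dqe.dqe0' must be in (0, 1]", call. = FALSE)
  }
  if (!(cfg$scan$max_tilt > 0 && cfg$scan$max_tilt <= 90)) {
    stop("configuration key 'scan.max_tilt' must be in (0, 90]", call. = FALSE)
  }
  if (!cfg$scan$mode %in% c("fixed_count", "fixed_increment")) {
    stop("configuration key 'scan.mode' must be fixed_count or fixed_increment",
         call. = FALSE)
  }
  if (cfg$scan$mode == "fixed_count" && cfg$scan$num_images < 1) {
    stop("configuration key 'scan.num_images' must be >= 1", call. = FALSE)
  }
  if (cfg$scan$mode == "fixed_increment") {
    check_positive(cfg$scan$increment, "scan.increment")
  }
  if (!cfg$scan$ordering %in% c("dose_symmetric", "sequential")) {
    stop("configuration key 'scan.ordering' must be dose_symmetric or sequential",
         call. = FALSE)
  }
  check_positive(cfg$scan$exposure, "scan.exposure")
  check_positive(cfg$simulation$slice_thickness, "simulation.slice_thickness")
  check_positive(cfg$simulation$pixel_size, "simulation.pixel_size")
  check_nonneg(cfg$simulation$damage_sensitivity, "simulation.damage_sensitivity")
  if (!(is.numeric(cfg$simulation$mean_free_path) &&
          cfg$simulation$mean_free_path > 0)) {
    stop("configuration key 'simulation.mean_free_path' must be > 0 (use Inf to disable)",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Load a simulation configuration from YAML
#'
#' Parses a YAML document and merges it over the documented defaults
#' ([default_config()]). Unknown keys are rejected with their full key path;
#' violated invariants are rejected with the constraint text. An empty
#' document yields the defaults.
#'
#' @param yaml_text YAML source text, or a length-1 path to a YAML file.
#' @return A validated `twin_config` list.
#' @examples
#' cfg <- load_config("beam:\n  energy: 200\n")
#' cfg$beam$energy
#' @export
load_config <- function(yaml_text = "") {
  if (length(yaml_text) == 1 && file.exists(yaml_text)) {
    user <- yaml::read_yaml(yaml_text)
  } else {
    user <- yaml::yaml.load(paste(yaml_text, collapse = "\n"))
  }
  cfg <- merge_config(unclass(default_config()), user)
  class(cfg) <- "twin_config"
  validate_config(cfg)
  cfg
}

#' Serialise a configuration back to YAML
#'
#' @param cfg A `twin_config` list.
#' @param path Optional file to write to.
#' @return The YAML text, invisibly when written to a file.
#' @export
save_config <- function(cfg, path = NULL) {
  txt <- yaml::as.yaml(unclass(cfg))
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Expand a scan model into an ordered acquisition plan
#'
#' Computes the tilt angles implied by the scan mode and orders them by the
#' acquisition scheme. In `fixed_count` mode exactly `num_images` angles are
#' spaced uniformly over `[-max_tilt, +max_tilt]` including both endpoints;
#' in `fixed_increment` mode angles step by `increment` degrees away from
#' zero out to `max_tilt`. The `dose_symmetric` ordering acquires projections
#' in increasing order of absolute tilt starting nearest 0 degrees, taking
#' the positive member of each +/- pair first (documented tie rule);
#' `sequential` ordering sweeps from `-max_tilt` to `+max_tilt`.
#'
#' @param scan The `scan` component of a [default_config()]-shaped list.
#' @return A data.frame in acquisition order with columns `index`
#'   (acquisition index), `angle` (degrees), `exposure` (s) and
#'   `cumulative_exposure` (s, strictly increasing).
#' @examples
#' plan <- generate_scan(list(max_tilt = 60, mode = "fixed_increment",
#'                            increment = 2, exposure = 1,
#'                            ordering = "sequential"))
#' nrow(plan) # 61
#' @export
generate_scan <- function(scan) {
  max_tilt <- scan$max_tilt
  stopifnot(max_tilt > 0, max_tilt <= 90)
  mode <- scan$mode %||% "fixed_count"
  ordering <- scan$ordering %||% "dose_symmetric"
  exposure <- scan$exposure %||% 1
  if (mode == "fixed_count") {
    n <- scan$num_images
    if (is.null(n) || n < 1) stop("scan.num_images must be >= 1")
    angles <- if (n == 1) 0 else seq(-max_tilt, max_tilt, length.out = n)
  } else if (mode == "fixed_increment") {
    inc <- scan$increment
    if (is.null(inc) || inc <= 0) stop("scan.increment must be > 0")
    pos <- seq(0, max_tilt, by = inc)
    angles <- sort(unique(c(-pos, pos)))
  } else {
    stop("unknown scan mode '", mode, "'")
  }
  if (ordering == "dose_symmetric") {
    # increasing |angle|; positive branch first on ties
    angles <- angles[order(abs(angles), -sign(angles))]
  } else {
    angles <- sort(angles)
  }
  n <- length(angles)
  data.frame(
    index = seq_len(n),
    angle = angles,
    exposure = rep(exposure, n),
    cumulative_exposure = cumsum(rep(exposure, n))
  )
}
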