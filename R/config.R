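# Run configuration: a flat YAML document (or plain named list) validated
# and normalized to strict SI.  Defaults reproduce the study box: the eight
# anchor compositions, D in 1-20 nm, H in 10-50 kA/m, f in 100-500 kHz,
# epsilon = 0.1, tau0 = 1e-9 s, T = 300 K, limit product 5e9 A Hz/m.

#' Parse a physical quantity with an optional unit suffix
#'
#' Accepts a bare number or a string such as `"20 kA/m"`, `"250 kHz"`,
#' `"16 nm"`, `"300 K"`, `"1e-9 s"` and returns the value in SI base units
#' (A/m, Hz, m, K, s).
#'
#' @param value A number, or a string `"<number> <unit>"`.
#' @return The SI value as a double, vectorized.
#' @examples
#' parse_quantity("20 kA/m")
#' parse_quantity("250 kHz")
#' @export
parse_quantity <- function(value) {
  if (is.numeric(value)) return(as.double(value))
  scale <- c("A/m" = 1, "kA/m" = 1e3, "Hz" = 1, "kHz" = 1e3, "MHz" = 1e6,
             "m" = 1, "nm" = 1e-9, "K" = 1, "s" = 1, "ns" = 1e-9)
  vapply(as.character(value), function(v) {
    m <- regmatches(v, regexec("^\\s*([-+0-9.eE]+)\\s*([A-Za-z/]*)\\s*$", v))[[1]]
    if (length(m) == 0L || is.na(suppressWarnings(num <- as.numeric(m[2])))) {
      abort(sprintf("cannot parse quantity '%s'.", v),
            class = "ferroheat_config_error")
    }
    unit <- m[3]
    if (unit == "") return(num)
    if (!unit %in% names(scale)) {
      abort(sprintf("unknown unit '%s' in '%s' (known: %s).",
                    unit, v, paste(names(scale), collapse = ", ")),
            class = "ferroheat_config_error")
    }
    num * scale[[unit]]
  }, numeric(1), USE.NAMES = FALSE)
}

#' Default run configuration
#'
#' @return A named list of class `run_config` holding the study defaults;
#'   see [validate_config()] for the key set and units.
#' @export
default_config <- function() {
  validate_config(list())
}

config_keys <- function() {
  c("x", "epsilon", "tau0", "T", "H", "f", "D_range",
    "limit_product", "threshold", "H_cap", "saturation_rel_gain", "H_grid")
}

#' Validate and normalize a run configuration
#'
#' Accepts a named list or a path to a flat YAML file.  Every value may be
#' given as an SI number or a unit-suffixed string (see [parse_quantity()]).
#' Unknown keys are rejected by name; missing keys take the documented
#' defaults; all outputs are SI.
#'
#' Keys: `x` (compositions in \[0,1\]), `epsilon`, `tau0` (s), `T` (K),
#' `H` (A/m, field grid), `f` (Hz, frequency grid), `D_range` (m, length 2),
#' `limit_product` (A Hz/m), `threshold` (W/g), `H_cap` (A/m),
#' `saturation_rel_gain`, `H_grid` (A/m, window grid).
#'
#' @param config A named list, or a length-1 character path to a YAML file.
#' @return A fully defaulted SI `run_config` list.
#' @examples
#' cfg <- validate_config(list(T = "310 K", H = c("20 kA/m")))
#' cfg$T
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) {
    abort("config must be a named list or a YAML file path.",
          class = "ferroheat_config_error")
  }
  unknown <- setdiff(names(config), config_keys())
  if (length(unknown) > 0L) {
    abort(sprintf("unknown config key(s): %s.", paste(unknown, collapse = ", ")),
          class = "ferroheat_config_error")
  }
  get_q <- function(key, default) {
    v <- config[[key]]
    if (is.null(v)) default else parse_quantity(v)
  }
  cfg <- list(
    x = get_q("x", c(0, 0.05, 0.1, 0.2, 0.4, 0.67, 0.8, 1)),
    epsilon = get_q("epsilon", 0.1),
    tau0 = get_q("tau0", 1e-9),
    T = get_q("T", 300),
    H = get_q("H", seq(10e3, 50e3, by = 10e3)),
    f = get_q("f", c(100e3, 250e3, 500e3)),
    D_range = get_q("D_range", c(1e-9, 20e-9)),
    limit_product = get_q("limit_product", 5e9),
    threshold = get_q("threshold", 10),
    H_cap = get_q("H_cap", 50e3),
    saturation_rel_gain = get_q("saturation_rel_gain", 0.05),
    H_grid = get_q("H_grid", seq(10e3, 50e3, by = 10e3))
  )
  if (length(cfg$x) == 0L) {
    abort("composition list `x` is empty.", class = "ferroheat_config_error")
  }
  check_range(cfg$x, "x", 0, 1)
  check_range(cfg$epsilon, "epsilon", 0, 1, lower_open = TRUE)
  check_range(cfg$tau0, "tau0", 0, lower_open = TRUE)
  check_range(cfg$T, "T", 0, lower_open = TRUE)
  check_range(cfg$H, "H", 0)
  check_range(cfg$f, "f", 0)
  if (length(cfg$D_range) != 2L || cfg$D_range[1] <= 0 ||
      cfg$D_range[2] <= cfg$D_range[1]) {
    abort("`D_range` must be two increasing positive lengths in m.",
          class = "ferroheat_config_error")
  }
  check_range(cfg$limit_product, "limit_product", 0, lower_open = TRUE)
  check_range(cfg$threshold, "threshold", 0, lower_open = TRUE)
  structure(cfg, class = "run_config")
}

#' Write a run configuration to YAML
#'
#' Emits the configuration as flat SI-valued YAML; re-reading it with
#' [validate_config()] round-trips to an identical configuration.
#'
#' @param config A `run_config` list.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
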