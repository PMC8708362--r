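# End-to-end report generation: recomputes every published reference table
# of the model (optima at fixed H, bio-limit optima, operating windows) and
# writes CSV/JSON products plus a per-cell comparison against the shipped
# reference values.

read_reference <- function(file) {
  path <- system.file("extdata", file, package = "ferroheat")
  as_tibble(utils::read.csv(path))
}

#' Published reference values reproduced by the model
#'
#' Reference tables of maximum loss power and optimal diameter from the
#' published study this model reproduces, shipped as plain CSV fixtures for
#' regression comparison: `reference_optima()` (per-composition optima at
#' H = 20 kA/m, f = 100/250/500 kHz; one truncated diameter entry is `NA`),
#' `reference_limit_optima()` (bio-limit optima for H = 10-50 kA/m at
#' `H x f = 5e9` A Hz/m) and `reference_windows()` (recommended operating
#' windows).
#'
#' @return A tibble; columns carry their units in the names
#'   (`*_W_per_g`, `*_nm`, `*_kA_per_m`, `*_kHz`).
#' @examples
#' reference_optima()
#' @export
reference_optima <- function() read_reference("reference_optima.csv")

#' @rdname reference_optima
#' @export
reference_limit_optima <- function() read_reference("reference_limit_optima.csv")

#' @rdname reference_optima
#' @export
reference_windows <- function() read_reference("reference_windows.csv")

round_tbl <- function(tbl) {
  mutate(tbl,
         across(dplyr::any_of(c("PsM_W_per_g", "PsMl_W_per_g")), ~ round(.x, 2)),
         across(dplyr::any_of(c("D_M_nm", "D_Mo_nm")), ~ round(.x, 1)))
}

write_products <- function(tbl, stem, out_dir, formats) {
  if ("csv" %in% formats) {
    readr::write_csv(round_tbl(tbl), file.path(out_dir, paste0(stem, ".csv")))
  }
  if ("json" %in% formats) {
    jsonlite::write_json(tbl, file.path(out_dir, paste0(stem, ".json")),
                         dataframe = "rows", digits = NA, auto_unbox = TRUE)
  }
  invisible(tbl)
}

#' Recompute the full study and compare against the reference tables
#'
#' Runs the whole pipeline at the configured study box and writes, under
#' `out_dir`:
#' * `optima_by_frequency.{csv,json}` -- per-composition `(D_M, PsM)` at
#'   each configured frequency and H = 20 kA/m;
#' * `limit_optima.{csv,json}` -- bio-limit optima over the H grid;
#' * `operating_windows.json` -- per-composition recommended windows;
#' * `psm_vs_x.csv`, `dm_vs_frequency.csv`, `psml_vs_field.csv` -- the
#'   curve products;
#' * `surfaces/surface_x*.csv` -- the `Ps(D, f)` surfaces (optional);
#' * `comparison.csv` -- per-cell relative error of every recomputed value
#'   against the shipped reference tables.
#'
#' CSV values are rounded to the reference precision (two decimals for
#' powers in W/g, 0.1 nm for diameters); JSON mirrors keep full precision.
#'
#' @param config A `run_config` (see [validate_config()]); defaults to
#'   [default_config()].
#' @param out_dir Output directory, created if missing.
#' @param formats Subset of `c("csv", "json")`.
#' @param surfaces Also write the (slow, large) surface grids? Default FALSE.
#' @param quiet Suppress the provenance log? Default FALSE.
#' @return Invisibly, a named list of the computed tibbles (`optima`,
#'   `limit_optima`, `windows`, `psml`, `dm`, `comparison`).
#' @export
reproduce_study <- function(config = default_config(), out_dir = tempdir(),
                            formats = c("csv", "json"), surfaces = FALSE,
                            quiet = FALSE) {
  config <- if (inherits(config, "run_config")) config else validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!quiet) {
    message(sprintf(
      "ferroheat run: T = %g K, tau0 = %g s, epsilon = %g, H x f limit = %g A Hz/m, %d compositions",
      config$T, config$tau0, config$epsilon, config$limit_product, length(config$x)))
  }

  optima <- psm_vs_x(config$x, H = 20e3, f = config$f,
                     D_range = config$D_range, epsilon = config$epsilon,
                     tau0 = config$tau0, T = config$T) |>
    display_units_optima()
  write_products(optima, "optima_by_frequency", out_dir, formats)
  readr::write_csv(select(optima, all_of(c("x", "f_kHz", "PsM_W_per_g"))),
                   file.path(out_dir, "psm_vs_x.csv"))

  dm <- dm_vs_frequency(config$x, f = config$f, H = 20e3,
                        D_range = config$D_range, epsilon = config$epsilon,
                        tau0 = config$tau0, T = config$T) |>
    mutate(f_kHz = .data$f / 1e3, D_M_nm = .data$D_M * 1e9) |>
    select(all_of(c("x", "f_kHz", "D_M_nm")))
  readr::write_csv(dm, file.path(out_dir, "dm_vs_frequency.csv"))

  lim <- limit_optimum(config$x, config$H, limit = config$limit_product,
                       D_range = config$D_range, epsilon = config$epsilon,
                       tau0 = config$tau0, T = config$T) |>
    display_units_limit()
  write_products(lim, "limit_optima", out_dir, formats)

  psml <- psml_vs_field(config$x, config$H, limit = config$limit_product,
                        D_range = config$D_range, epsilon = config$epsilon,
                        tau0 = config$tau0, T = config$T)
  readr::write_csv(
    mutate(psml, H_kA_per_m = .data$H / 1e3, f_l_kHz = .data$f_l / 1e3) |>
      select(all_of(c("x", "H_kA_per_m", "f_l_kHz", "PsM_l", "dPsM_dH"))),
    file.path(out_dir, "psml_vs_field.csv"))

  windows <- purrr::map(config$x, function(xi_) {
    operating_window(xi_, limit = config$limit_product,
                     threshold = config$threshold, H_cap = config$H_cap,
                     saturation_rel_gain = config$saturation_rel_gain,
                     H_grid = config$H_grid, D_range = config$D_range,
                     epsilon = config$epsilon, tau0 = config$tau0, T = config$T)
  }) |> bind_rows()
  jsonlite::write_json(windows, file.path(out_dir, "operating_windows.json"),
                       dataframe = "rows", digits = NA, auto_unbox = TRUE)

  if (surfaces) {
    surf_dir <- file.path(out_dir, "surfaces")
    dir.create(surf_dir, showWarnings = FALSE)
    for (xi_ in config$x) {
      surf <- ps_surface(xi_, D = seq(config$D_range[1], config$D_range[2],
                                      by = 1e-10),
                         f = config$f, H = 20e3, epsilon = config$epsilon,
                         tau0 = config$tau0, T = config$T)
      readr::write_csv(surf, file.path(surf_dir, sprintf("surface_x%s.csv", xi_)))
    }
  }

  comparison <- compare_to_reference(optima, lim)
  readr::write_csv(comparison, file.path(out_dir, "comparison.csv"))

  invisible(list(optima = optima, limit_optima = lim, windows = windows,
                 psml = psml, dm = dm, comparison = comparison))
}

display_units_optima <- function(optima) {
  mutate(optima,
         H_kA_per_m = .data$H / 1e3, f_kHz = .data$f / 1e3,
         D_M_nm = .data$D_M * 1e9, PsM_W_per_g = .data$PsM) |>
    select(all_of(c("x", "H_kA_per_m", "f_kHz", "D_M_nm", "PsM_W_per_g")))
}

display_units_limit <- function(lim) {
  mutate(lim,
         H_kA_per_m = .data$H / 1e3, f_l_kHz = .data$f_l / 1e3,
         D_Mo_nm = .data$D_Mo * 1e9, PsMl_W_per_g = .data$PsM_l) |>
    select(all_of(c("H_kA_per_m", "f_l_kHz", "x", "PsMl_W_per_g", "D_Mo_nm")))
}

compare_to_reference <- function(optima, lim) {
  ref_opt <- reference_optima() |>
    rename(ref_PsM = "PsM_W_per_g", ref_DM = "DM_nm")
  cmp1 <- optima |>
    mutate(f_kHz = round(.data$f_kHz)) |>
    dplyr::inner_join(ref_opt, by = c("x", "f_kHz", "H_kA_per_m")) |>
    mutate(table = "optima",
           rel_err_Ps = abs(.data$PsM_W_per_g - .data$ref_PsM) / .data$ref_PsM,
           abs_err_D_nm = abs(.data$D_M_nm - .data$ref_DM)) |>
    select(all_of(c("table", "x", "f_kHz", "H_kA_per_m",
                    "rel_err_Ps", "abs_err_D_nm")))
  ref_lim <- reference_limit_optima() |>
    select(-all_of("f_l_kHz")) |>
    rename(ref_PsM = "PsMl_W_per_g", ref_DM = "DMo_nm")
  cmp2 <- lim |>
    dplyr::inner_join(ref_lim, by = c("x", "H_kA_per_m")) |>
    mutate(table = "limit_optima", f_kHz = round(.data$f_l_kHz),
           rel_err_Ps = abs(.data$PsMl_W_per_g - .data$ref_PsM) / .data$ref_PsM,
           abs_err_D_nm = abs(.data$D_Mo_nm - .data$ref_DM)) |>
    select(all_of(c("table", "x", "f_kHz", "H_kA_per_m",
                    "rel_err_Ps", "abs_err_D_nm")))
  bind_rows(cmp1, cmp2)
}
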