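#' Packaged validation tables
#'
#' Loads the proof-of-concept validation datasets shipped with the package,
#' recorded on a head-up-tilt suspension hypogravity analogue:
#'
#' * `manikin_graded` - condition-level summary of a manikin suspended 30
#'   times at each of six graded simulated gravity levels (0-0.20 g):
#'   foot-plate angle, manikin orientation relative to the plate, target and
#'   measured loading (%BW, mean and sd).
#' * `manikin_random` - same schema for nine randomly generated gravity
#'   levels between 0 and 0.20 g, 3 trials per condition (one level was
#'   dropped because the manikin failed to contact the platform).
#' * `standing_study1` - 15 participants standing in simulated lunar gravity
#'   (9.5 deg head-up tilt), one visit: Earth body mass, measured lunar body
#'   mass (includes the 16.4 kg back-support plate's axial contribution),
#'   loading (%BW) and error from the 16.5 %BW target.
#' * `standing_study2` - 19 participants, simulated lunar gravity on up to
#'   three separate days (14 complete cases): per-visit loading (%BW) and
#'   error; missing visits are `NA`.
#'
#' @param name One of `"manikin_graded"`, `"manikin_random"`,
#'   `"standing_study1"`, `"standing_study2"`.
#' @return A typed tibble; missing cells are `NA`, never zero.
#' @examples
#' validation_table("standing_study1")
#' @export
validation_table <- function(name) {
  valid <- c("manikin_graded", "manikin_random",
             "standing_study1", "standing_study2")
  if (!is.character(name) || length(name) != 1 || !name %in% valid) {
    abort(paste0("`name` must be one of: ", paste(valid, collapse = ", ")))
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "hutsim",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  na = "NA")
}

#' Per-visit loading in long format with complete-case filtering
#'
#' Reshapes the three-visit standing table into long format
#' (`participant`, `visit`, `loading_pct`), optionally keeping only
#' participants measured at every visit. Complete-case extraction is
#' deterministic and preserves participant order.
#'
#' @param data A wide loading table with columns `participant` and
#'   `loading_v*` (as returned by `validation_table("standing_study2")`).
#' @param complete_cases Keep only participants with no missing visit
#'   (default FALSE).
#' @return A long tibble `participant`, `visit` (e.g. "v1"), `loading_pct`.
#' @examples
#' loading_long(validation_table("standing_study2"), complete_cases = TRUE)
#' @export
loading_long <- function(data, complete_cases = FALSE) {
  long <- tidyr::pivot_longer(
    dplyr::select(data, "participant", dplyr::starts_with("loading_")),
    dplyr::starts_with("loading_"),
    names_to = "visit", names_prefix = "loading_",
    values_to = "loading_pct")
  if (complete_cases) {
    complete <- dplyr::summarise(dplyr::group_by(long, .data$participant),
                                 ok = !anyNA(.data$loading_pct),
                                 .groups = "drop")
    long <- dplyr::semi_join(long, dplyr::filter(complete, .data$ok),
                             by = "participant")
  }
  long
}
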