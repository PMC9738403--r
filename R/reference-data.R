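#' Reference nearest-neighbour statistics for medical facility classes
#'
#' Reported nearest-neighbour statistics for six medical facility classes
#' (tertiary-A, general and specialist hospitals, community-level
#' hospitals, clinics, pharmacies) and two public-transport station types
#' (rail, bus) in a large polycentric mountainous metropolis: the observed
#' mean nearest-neighbour distance `r1bar_m`, its expectation under
#' complete spatial randomness `rebar_m`, the reported ratio `R_reported`
#' (2 decimal places) and the resulting spatial-structure label. All eight
#' rows are strongly clustered (`R < 1`). Feeding each (`r1bar_m`,
#' `rebar_m`) pair to [nn_ratio()] reproduces `R_reported` at the printed
#' precision; the table is used for examples and validation.
#'
#' @return A tibble with columns `class`, `r1bar_m`, `rebar_m`,
#'   `R_reported`, `spatial_structure_type`.
#' @export
#' @examples
#' ref <- facility_nn_reference()
#' nn_ratio(ref$r1bar_m, ref$rebar_m)
facility_nn_reference <- function() {
  path <- system.file("extdata", "facility_nn_reference.csv",
                      package = "medaccess", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}
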