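#' Reported reef-fish benchmark mAP values
#'
#' Published mAP (%) of three single-shot detector configurations on a
#' large long-tailed reef-fish survey benchmark, trained with plain
#' cross-entropy (`ce_map`) and retrained with the class-aware loss
#' (`cace_map`). These numbers are inputs for improvement arithmetic;
#' the package does not (and at desk scale cannot) retrain those
#' full-size models.
#'
#' @return A tibble: `backbone`, `ce_map`, `cace_map`.
#' @export
reported_benchmark <- function() {
  readr::read_csv(system.file("extdata", "reported_benchmark.csv",
                              package = "ltdetect"),
                  col_types = readr::cols(
                    backbone = readr::col_character(),
                    ce_map = readr::col_double(),
                    cace_map = readr::col_double()
                  ))
}

#' Improvement arithmetic over a benchmark table
#'
#' For each row computes the absolute mAP increment
#' `cace_map - ce_map` and the relative improvement
#' `100 * (cace_map - ce_map) / ce_map` (in percent of the baseline).
#'
#' @param benchmark A tibble with `ce_map` and `cace_map` columns;
#'   default [reported_benchmark()].
#' @return The input with `map_increment` and `relative_improvement_pct`
#'   columns appended.
#' @examples
#' improvement_summary()
#' @export
improvement_summary <- function(benchmark = reported_benchmark()) {
  dplyr::mutate(benchmark,
    map_increment = .data$cace_map - .data$ce_map,
    relative_improvement_pct = 100 * (.data$cace_map - .data$ce_map) / .data$ce_map)
}
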