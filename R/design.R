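#' Design calculators: sample processing time
#'
#' Time to push a sample volume through a device at a given volumetric
#' flow rate.
#'
#' @param sample_volume_ul Sample volume (uL).
#' @param flow_rate_ul_min Volumetric flow rate (uL/min).
#' @return A tibble with `minutes` and `hours`.
#' @examples
#' processing_time(100, 0.5) # 200 min = 3.3 h
#' processing_time(100, 10) # 10 min
#' @export
processing_time <- function(sample_volume_ul, flow_rate_ul_min) {
  stopifnot(sample_volume_ul >= 0)
  if (!is.finite(flow_rate_ul_min) || flow_rate_ul_min <= 0) {
    stop("`flow_rate_ul_min` must be positive", call. = FALSE)
  }
  minutes <- sample_volume_ul / flow_rate_ul_min
  tibble::tibble(minutes = minutes, hours = minutes / 60)
}

#' Design calculators: throughput ratio of two devices
#'
#' Ratio of total raw cross-sectional flow areas (sum of width x depth
#' over parallel beds; the single-bed value for a serial flow path),
#' i.e. the flow-rate ratio at matched mean channel velocity. With
#' `pillar_corrected = TRUE` the open (pillar-row) cross-sections are
#' used instead.
#'
#' @param device_a,device_b `device_geometry` objects.
#' @param pillar_corrected Use open cross-sections instead of raw ones.
#' @return Numeric ratio (throughput of `device_a` relative to
#'   `device_b`).
#' @export
throughput_ratio <- function(device_a, device_b, pillar_corrected = FALSE) {
  area <- function(device) {
    device <- as_device(device)
    per_bed <- vapply(device$beds, function(bed) {
      if (pillar_corrected) bed_open_cross_section(bed)
      else bed$width * bed$depth
    }, numeric(1))
    if (device$arrangement == "parallel") sum(per_bed) else per_bed[[1]]
  }
  a <- area(device_a)
  b <- area(device_b)
  if (a <= 0 || b <= 0) stop("zero cross-sectional area", call. = FALSE)
  a / b
}

#' Design calculators: assay timeline
#'
#' Totals a sequence of assay stages and returns the per-stage breakdown.
#'
#' @param stages A data frame (or tibble) with columns `label` and
#'   `minutes`, or a named numeric vector of stage durations in minutes.
#' @return A tibble with one row per stage plus a `TOTAL` row; total also
#'   reported in hours.
#' @examples
#' assay_timeline(c(enrichment = 50, lysis_SPE = 60, RT = 60, ddPCR = 50))
#' @export
assay_timeline <- function(stages) {
  if (is.numeric(stages)) {
    stages <- tibble::tibble(
      label = names(stages) %||% paste0("stage_", seq_along(stages)),
      minutes = as.numeric(stages)
    )
  }
  stages <- tibble::as_tibble(stages)
  if (nrow(stages) == 0) {
    return(tibble::tibble(label = "TOTAL", minutes = 0, hours = 0))
  }
  stopifnot(all(c("label", "minutes") %in% names(stages)),
            all(stages$minutes >= 0))
  total <- sum(stages$minutes)
  dplyr::bind_rows(
    dplyr::mutate(stages, hours = .data$minutes / 60),
    tibble::tibble(label = "TOTAL", minutes = total, hours = total / 60)
  )
}
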