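#' Omega-6 and omega-3 desaturation efficiencies
#'
#' The desaturation efficiency (DE) of a step in the C18 cascade
#' (18:1 -> 18:2 -> 18:3) is the proportion of available substrate converted
#' to downstream product(s):
#' omega-6 DE = (18:2 + 18:3) / (18:1 + 18:2 + 18:3) and
#' omega-3 DE = 18:3 / (18:2 + 18:3).
#' A zero denominator makes the corresponding efficiency undefined; it is
#' reported as `NA`, never as 0 or infinity.
#'
#' @param data Data frame of fatty-acid mass fractions with columns
#'   `C18:1`, `C18:2`, `C18:3` (one row per sample; extra columns are kept).
#' @return `data` with columns `omega6_de` and `omega3_de` appended.
#' @export
#' @examples
#' desaturation_efficiency(
#'   tibble::tibble(`C18:1` = 0.4, `C18:2` = 0.3, `C18:3` = 0.2)
#' )
desaturation_efficiency <- function(data) {
  need <- c("C18:1", "C18:2", "C18:3")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop_oilnet(paste0("missing fatty-acid column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  oa <- data[["C18:1"]]; la <- data[["C18:2"]]; ala <- data[["C18:3"]]
  if (any(c(oa, la, ala) < 0, na.rm = TRUE)) {
    stop_oilnet("fatty-acid fractions must be non-negative")
  }
  den6 <- oa + la + ala
  den3 <- la + ala
  dplyr::mutate(as_tibble(data),
    omega6_de = ifelse(den6 > 0, (la + ala) / den6, NA_real_),
    omega3_de = ifelse(den3 > 0, ala / den3, NA_real_)
  )
}

#' Saturation ratios of a fatty-acid profile
#'
#' SFA:UFA (saturated to unsaturated) and MUFA:PUFA (monounsaturated to
#' polyunsaturated) ratios, with SFA = C16:0 + C18:0 + C20:0 + C22:0,
#' MUFA = C18:1 and PUFA = C18:2 + C18:3. Zero denominators give `NA`.
#'
#' @param data Data frame of fatty-acid mass fractions; any of the standard
#'   keys absent are treated as zero, but at least one key must be present
#'   and each row must have positive total mass.
#' @return `data` with columns `sfa_ufa` and `mufa_pufa` appended.
#' @export
saturation_ratios <- function(data) {
  present <- intersect(c(.sfa_keys, .mufa_keys, .pufa_keys), names(data))
  if (!length(present)) stop_oilnet("no recognised fatty-acid columns")
  get_sum <- function(keys) {
    ks <- intersect(keys, names(data))
    if (!length(ks)) return(rep(0, nrow(data)))
    rowSums(as.matrix(data[, ks, drop = FALSE]))
  }
  sfa <- get_sum(.sfa_keys)
  mufa <- get_sum(.mufa_keys)
  pufa <- get_sum(.pufa_keys)
  if (any(sfa + mufa + pufa <= 0)) {
    stop_oilnet("all-zero fatty-acid profile")
  }
  dplyr::mutate(as_tibble(data),
    sfa_ufa = ifelse(mufa + pufa > 0, sfa / (mufa + pufa), NA_real_),
    mufa_pufa = ifelse(pufa > 0, mufa / pufa, NA_real_)
  )
}

#' Regroup minor fatty acids into a single category
#'
#' Collapses the long-chain saturated fatty acids C20:0 and C22:0 into the
#' `other` column, the grouping used when plotting composition bar charts.
#'
#' @param data Data frame of fatty-acid fractions.
#' @return `data` with C20:0/C22:0 folded into `other`.
#' @export
group_minor_fas <- function(data) {
  minor <- intersect(c("C20:0", "C22:0"), names(data))
  if (!length(minor)) return(as_tibble(data))
  other <- if ("other" %in% names(data)) data[["other"]] else 0
  out <- dplyr::mutate(as_tibble(data),
    other = other + rowSums(as.matrix(data[, minor, drop = FALSE]))
  )
  out[setdiff(names(out), minor)]
}

#' Relative expression by the 2^-ddCt method
#'
#' Computes qPCR relative expression 2^-(dCt_sample - dCt_calibrator) with
#' dCt = Ct(target) - Ct(reference).
#'
#' @param data Data frame with columns `ct_target` and `ct_reference` (one
#'   row per sample/reaction).
#' @param calibrator Either a single row of the same shape or a named list /
#'   vector with `ct_target` and `ct_reference` for the calibrator sample.
#' @return `data` with columns `ddct` and `fold_change` appended.
#' @export
relative_expression <- function(data, calibrator) {
  need <- c("ct_target", "ct_reference")
  if (!all(need %in% names(data))) {
    stop_oilnet("`data` needs columns ct_target and ct_reference")
  }
  cal <- as.list(calibrator)
  if (!all(need %in% names(cal))) {
    stop_oilnet("`calibrator` needs ct_target and ct_reference")
  }
  if (any(data$ct_target <= 0 | data$ct_reference <= 0) ||
      cal$ct_target <= 0 || cal$ct_reference <= 0) {
    stop_oilnet("Ct values must be positive")
  }
  dct <- data$ct_target - data$ct_reference
  dct_cal <- cal$ct_target - cal$ct_reference
  dplyr::mutate(as_tibble(data),
    ddct = dct - dct_cal,
    fold_change = 2^(-(dct - dct_cal))
  )
}

#' Summarise oil accumulation dynamics over development
#'
#' Per stage: mean oil content, standard error (NA with a single replicate),
#' and increment over the previous stage mean. Flags the stage of maximal
#' oil content (`is_peak`) and the onset of rapid accumulation (`is_onset`):
#' the first stage whose increment exceeds `onset_frac` of the full range of
#' the stage-mean series. A flat series has no onset.
#'
#' @param data Data frame with columns `stage_daf` and `oil_content`
#'   (optionally `replicate`).
#' @param onset_frac Fraction of the series range an increment must exceed
#'   to mark onset; default 0.1.
#' @return Per-stage tibble with columns `stage_daf`, `oil_mean`, `oil_se`,
#'   `n`, `increment`, `is_peak`, `is_onset`.
#' @export
accumulation_summary <- function(data, onset_frac = 0.1) {
  if (!all(c("stage_daf", "oil_content") %in% names(data))) {
    stop_oilnet("`data` needs columns stage_daf and oil_content")
  }
  check_fraction(onset_frac, "onset_frac")
  stg <- unique(data$stage_daf)
  if (length(stg) < 2) stop_oilnet("need >= 2 stages")
  if (is.unsorted(stg, strictly = TRUE)) {
    stop_oilnet("stages must appear in increasing order")
  }
  per_stage <- data |>
    dplyr::group_by(.data$stage_daf) |>
    dplyr::summarise(
      oil_mean = mean(.data$oil_content),
      oil_se = ifelse(dplyr::n() > 1,
                      sd(.data$oil_content) / sqrt(dplyr::n()), NA_real_),
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(.data$stage_daf)
  rng <- diff(range(per_stage$oil_mean))
  inc <- c(NA_real_, diff(per_stage$oil_mean))
  onset <- if (rng > 0) which(inc > onset_frac * rng)[1] else NA_integer_
  dplyr::mutate(per_stage,
    increment = inc,
    is_peak = dplyr::row_number() ==
      which.max(per_stage$oil_mean),
    is_onset = !is.na(onset) & dplyr::row_number() == onset
  )
}
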