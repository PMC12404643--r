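#' Heart rate from the duration of five cardiac cycles
#'
#' The timing protocol records the interval from end systole to end
#' diastole over 5 cycles; rate in beats per minute is `(5 / t) * 60`.
#'
#' @param cycle_time_5beats Time for five beats, in seconds (vectorized).
#' @return Heart rate(s) in beats per minute.
#' @examples
#' heart_rate_bpm(2)   # 150 bpm
#' @export
heart_rate_bpm <- function(cycle_time_5beats) {
  t <- as.numeric(cycle_time_5beats)
  if (any(!is.finite(t)) || any(t <= 0))
    stop("cycle time must be positive and finite")
  (5 / t) * 60
}

#' Ventricular fractional area change
#'
#' Contractility proxy from ventricle cross-sectional areas:
#' `FAC = (area_diastole - area_systole) / area_diastole * 100` (percent).
#' Units cancel, so any consistent area unit works. A systolic area larger
#' than the diastolic one yields a negative FAC; it is returned as-is (the
#' caller can flag it) rather than rejected.
#'
#' @param area_diastole,area_systole Ventricle areas at end diastole and
#'   end systole (vectorized, same units).
#' @return FAC in percent.
#' @examples
#' fractional_area_change(100, 50)  # 50
#' @export
fractional_area_change <- function(area_diastole, area_systole) {
  d <- as.numeric(area_diastole); s <- as.numeric(area_systole)
  if (any(!is.finite(d)) || any(d <= 0))
    stop("area at diastole must be positive and finite")
  (d - s) / d * 100
}

#' Per-animal averages of replicate cardiac measurements
#'
#' Each animal is typically measured at three separate cardiac cycles; this
#' averages areas, heart rate, and FAC per animal. FAC is computed per
#' replicate and then averaged (`fac_mean`); the FAC of the averaged areas
#' (`fac_of_means`) is emitted alongside since the two conventions differ
#' slightly and source protocols rarely say which they used.
#'
#' @param measurements Data frame with columns `animal_id`,
#'   `area_diastole`, `area_systole` and optionally `cycle_time_5beats`.
#' @return Data frame with one row per animal: replicate count, mean areas,
#'   `fac_mean`, `fac_of_means`, `heart_rate_bpm` (if timing supplied), and
#'   `n_flagged_negative_fac`.
#' @export
average_replicates <- function(measurements) {
  need <- c("animal_id", "area_diastole", "area_systole")
  if (!all(need %in% names(measurements)))
    stop("measurements need columns: ", paste(need, collapse = ", "))
  has_time <- "cycle_time_5beats" %in% names(measurements)
  fac <- fractional_area_change(measurements$area_diastole,
                                measurements$area_systole)
  split_idx <- split(seq_len(nrow(measurements)),
                     as.character(measurements$animal_id))
  rows <- lapply(names(split_idx), function(id) {
    i <- split_idx[[id]]
    d <- mean(measurements$area_diastole[i])
    s <- mean(measurements$area_systole[i])
    out <- data.frame(
      animal_id = id, n_replicates = length(i),
      area_diastole = d, area_systole = s,
      fac_mean = mean(fac[i]),
      fac_of_means = fractional_area_change(d, s),
      n_flagged_negative_fac = sum(fac[i] < 0),
      stringsAsFactors = FALSE)
    if (has_time)
      out$heart_rate_bpm <- mean(heart_rate_bpm(measurements$cycle_time_5beats[i]))
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Delta-delta-Ct relative expression
#'
#' Standard qRT-PCR relative quantification: each sample's target Ct is
#' normalized to its reference-gene Ct (`dct = ct_target - ct_reference`),
#' then to the mean dCt of the control-group samples for that target
#' (`ddct`), and expressed as fold change `2^(-ddct)`. The raw `ddct` and
#' `log2_fold = -ddct` columns are always emitted so any alternative
#' transform can be applied downstream. By construction the geometric mean
#' of control fold changes is exactly 1.
#'
#' @param table Data frame with columns `sample_id`, `group`, `gene`, `ct`.
#'   Each sample must have exactly one reference-gene row.
#' @param reference_gene Housekeeping gene symbol used for normalization.
#' @param control_group Value of `group` identifying control samples.
#' @return Data frame with one row per sample x target gene: `sample_id`,
#'   `group`, `gene`, `dct`, `ddct`, `log2_fold`, `fold_change`.
#' @export
ddct_fold_change <- function(table, reference_gene, control_group = "control") {
  need <- c("sample_id", "group", "gene", "ct")
  if (!all(need %in% names(table)))
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  table$ct <- as.numeric(table$ct)
  if (any(!is.finite(table$ct))) stop("non-finite Ct value(s)")
  is_ref <- table$gene == reference_gene
  ref_count <- tapply(is_ref, table$sample_id, sum)
  bad <- names(ref_count)[ref_count != 1L]
  if (length(bad))
    stop("sample(s) without exactly one reference-gene Ct: ",
         paste(bad, collapse = ", "))
  ref_ct <- stats::setNames(table$ct[is_ref],
                            as.character(table$sample_id[is_ref]))
  tgt <- table[!is_ref, , drop = FALSE]
  if (!nrow(tgt)) stop("no target-gene rows in Ct table")
  tgt$dct <- tgt$ct - ref_ct[as.character(tgt$sample_id)]
  ctrl <- tgt$group == control_group
  if (!any(ctrl)) stop("no sample in control group '", control_group, "'")
  ctrl_mean <- tapply(tgt$dct[ctrl], tgt$gene[ctrl], mean)
  if (any(!unique(tgt$gene) %in% names(ctrl_mean)))
    stop("target gene(s) without any control sample: ",
         paste(setdiff(unique(tgt$gene), names(ctrl_mean)), collapse = ", "))
  tgt$ddct <- tgt$dct - as.numeric(ctrl_mean[tgt$gene])
  tgt$log2_fold <- -tgt$ddct
  tgt$fold_change <- 2^(-tgt$ddct)
  res <- tgt[, c("sample_id", "group", "gene", "dct", "ddct",
                 "log2_fold", "fold_change")]
  rownames(res) <- NULL
  res
}
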