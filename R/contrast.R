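#' Contrast ratio of a region against a reference region
#'
#' `CR = (mean(ROI) - mean(reference)) / mean(reference)` — the dominant
#' convention in the neuromelanin-MRI literature. CR is invariant under any
#' positive global rescaling of the volume, which makes it consistent with
#' reference-based intensity normalization.
#'
#' @param vol an `nm_volume`.
#' @param roi_mask,reference_mask non-empty logical arrays on the volume
#'   grid.
#' @return scalar CR.
#' @export
contrast_ratio <- function(vol, roi_mask, reference_mask) {
  roi_mean <- mask_mean(vol, roi_mask, "ROI mask")
  ref_mean <- mask_mean(vol, reference_mask, "reference mask")
  if (ref_mean <= 0)
    stop("reference-region mean must be positive for a contrast ratio",
         call. = FALSE)
  (roi_mean - ref_mean) / ref_mean
}

#' Volume-weighted mean of the N1 and N2 contrast ratios
#'
#' `(CR_N1 * area_N1 + CR_N2 * area_N2) / (area_N1 + area_N2)`, the
#' headline combined marker. Weights are ROI volumes in mm^3 (fixed
#' template-space areas, identical for every subject).
#'
#' @param cr_n1,cr_n2 contrast ratios.
#' @param area_n1,area_n2 ROI volumes in mm^3, non-negative and not both
#'   zero.
#' @return the area-weighted average.
#' @export
volume_weighted_mean <- function(cr_n1, area_n1, cr_n2, area_n2) {
  if (any(c(area_n1, area_n2) < 0))
    stop("areas must be non-negative", call. = FALSE)
  if (all(c(area_n1, area_n2) == 0))
    stop("at least one area must be positive", call. = FALSE)
  (cr_n1 * area_n1 + cr_n2 * area_n2) / (area_n1 + area_n2)
}

#' Region keys of the contrast-ratio table
#'
#' The eight per-side regions measured for every subject, in reporting
#' order.
#' @return character vector of column names.
#' @export
cr_regions <- function() {
  c("right_n1", "left_n1", "right_n2", "left_n2",
    "right_n1n2", "left_n1n2", "right_snpc", "left_snpc")
}

#' Per-subject contrast-ratio table
#'
#' Measures, for every subject volume in template space, the CR of N1, N2
#' and whole SNpc on each side plus the volume-weighted N1+N2 combination
#' (weights = template ROI volumes from the ROI set).
#'
#' @param cohort tibble with at least `subject_id` and `group`.
#' @param volumes named list of template-space `nm_volume`, keyed by
#'   subject id.
#' @param rois an `nm_roiset` (must contain `left_n1`, `left_n2`,
#'   `right_n1`, `right_n2`, `left_snpc`, `right_snpc`, `reference`).
#' @return tibble of class `nm_cr_table`: one row per subject, the eight CR
#'   columns of [cr_regions()], and `reference_mean`.
#' @export
build_cr_table <- function(cohort, volumes, rois) {
  labels <- rois$labels
  need <- c("left_n1", "right_n1", "left_n2", "right_n2",
            "left_snpc", "right_snpc", "reference")
  missing_lab <- setdiff(need, names(labels))
  if (length(missing_lab))
    stop("ROI set lacks labels: ", paste(missing_lab, collapse = ", "),
         call. = FALSE)
  vol_of <- function(lab)
    rois$volumes_mm3$volume_mm3[rois$volumes_mm3$label == lab]
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    sid <- cohort$subject_id[i]
    v <- volumes[[sid]]
    if (is.null(v))
      stop(sprintf("missing template-space volume for subject %s", sid),
           call. = FALSE)
    cr <- function(lab) contrast_ratio(v, labels[[lab]], labels$reference)
    out <- list(subject_id = sid, group = cohort$group[i])
    for (side in c("right", "left")) {
      c1 <- cr(paste0(side, "_n1"))
      c2 <- cr(paste0(side, "_n2"))
      out[[paste0(side, "_n1")]] <- c1
      out[[paste0(side, "_n2")]] <- c2
      out[[paste0(side, "_n1n2")]] <- volume_weighted_mean(
        c1, vol_of(paste0(side, "_n1")), c2, vol_of(paste0(side, "_n2")))
      out[[paste0(side, "_snpc")]] <- cr(paste0(side, "_snpc"))
    }
    out$reference_mean <- mean(v$data[labels$reference])
    tibble::as_tibble(out)
  })
  out <- dplyr::bind_rows(rows)
  out <- out[, c("subject_id", "group", cr_regions(), "reference_mean")]
  class(out) <- c("nm_cr_table", class(out))
  out
}

#' Read/write a contrast-ratio table at full precision
#' @param cr_table an `nm_cr_table` tibble.
#' @param path CSV file path.
#' @export
write_cr_table <- function(cr_table, path) {
  df <- as.data.frame(cr_table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cr_table
#' @export
read_cr_table <- function(path) {
  # base read.csv: strtod round-trips the %.17g representation exactly
  out <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  class(out) <- c("nm_cr_table", class(out))
  out
}
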