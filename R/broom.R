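#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidiers for fitted result objects
#'
#' `tidy()` returns the per-element detail of a result (ROC curve points,
#' per-subject laterality calls, per-voxel statistics, per-label volumes);
#' `glance()` returns a one-row summary.
#'
#' @param x a result object.
#' @param ... unused.
#' @return a tibble.
#' @name nigramap-tidiers
NULL

#' @rdname nigramap-tidiers
#' @export
tidy.nm_roc <- function(x, ...) {
  dplyr::mutate(x$curve, region = x$region, .before = 1)
}

#' @rdname nigramap-tidiers
#' @export
glance.nm_roc <- function(x, ...) {
  tibble::tibble(region = x$region, auc = x$auc, ci_low = x$ci[1],
                 ci_high = x$ci[2], threshold = x$threshold,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 youden = x$youden, degenerate = x$degenerate)
}

#' @rdname nigramap-tidiers
#' @export
tidy.nm_roc_comparison <- function(x, ...) x$pairs

#' @rdname nigramap-tidiers
#' @export
tidy.nm_laterality <- function(x, ...) x$subjects

#' @rdname nigramap-tidiers
#' @export
glance.nm_laterality <- function(x, ...) {
  tibble::tibble(n_determinate = x$n_determinate,
                 n_concordant = x$n_concordant,
                 fisher_p = x$fisher_p)
}

#' @rdname nigramap-tidiers
#' @export
tidy.nm_statmap <- function(x, ...) {
  idx <- which(x$mask)
  pos <- arrayInd(idx, dim(x$mask))
  tibble::tibble(i = pos[, 1], j = pos[, 2], k = pos[, 3],
                 statistic = x$statistic[idx], p_raw = x$p_raw[idx],
                 p_corrected = x$p_corrected[idx])
}

#' @rdname nigramap-tidiers
#' @export
glance.nm_statmap <- function(x, ...) {
  tibble::tibble(
    n_voxels = sum(x$mask),
    n_significant = sum(x$p_corrected < 0.05 & x$statistic > 0,
                        na.rm = TRUE),
    n_flagged = sum(is.na(x$statistic[which(x$mask)])),
    n_perm = x$n_perm, df = x$df)
}

#' @rdname nigramap-tidiers
#' @export
tidy.nm_roiset <- function(x, ...) x$volumes_mm3
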