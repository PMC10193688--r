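#' Voxelwise two-sample comparison with permutation FWE control
#'
#' Computes a pooled-variance two-sample t statistic per voxel inside the
#' analysis mask (group A minus group B; by pipeline convention A = controls,
#' B = patients, so positive statistics mark signal loss in patients). Raw
#' two-sided p-values come from the t distribution; family-wise-error
#' corrected p-values come from the permutation distribution of the maximum
#' absolute statistic (max-T), which is exact under group exchangeability.
#'
#' Voxels with zero within-group variance in both groups are flagged
#' (`NA` statistic) and excluded from correction.
#'
#' @param group_a_volumes,group_b_volumes lists of `nm_volume` on a common
#'   (template) grid, at least 2 per group.
#' @param analysis_mask logical array on the same grid (template-space SNpc
#'   plus margin).
#' @param n_perm number of random permutations (default 1000).
#' @param seed RNG seed for the permutation draws.
#' @return object of class `nm_statmap`: arrays `statistic`, `p_raw`,
#'   `p_corrected` (NA outside the mask), the `mask`, group sizes, `df`,
#'   `n_perm`, and the permutation `max_t` distribution.
#' @export
voxelwise_test <- function(group_a_volumes, group_b_volumes, analysis_mask,
                           n_perm = 1000, seed = 1L) {
  na <- length(group_a_volumes); nb <- length(group_b_volumes)
  if (na < 2 || nb < 2) stop("need >= 2 subjects per group", call. = FALSE)
  grid <- group_a_volumes[[1]]
  if (!identical(dim(analysis_mask), dim(grid)))
    stop("analysis mask is not on the volume grid", call. = FALSE)
  idx <- which(analysis_mask)
  if (!length(idx)) stop("analysis mask is empty", call. = FALSE)
  x <- vapply(c(group_a_volumes, group_b_volumes),
              function(v) v$data[idx], numeric(length(idx)))
  n <- na + nb
  df <- n - 2

  t_stat_all <- function(ga) {
    # ga: n x B 0/1 indicator of group-A membership per permutation
    sa <- x %*% ga
    s2a <- (x^2) %*% ga
    tot <- rowSums(x); tot2 <- rowSums(x^2)
    ma <- sa / na
    mb <- (tot - sa) / nb
    ssa <- s2a - na * ma^2
    ssb <- (tot2 - s2a) - nb * mb^2
    sp2 <- (ssa + ssb) / df
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    tt <- (ma - mb) / se
    tt[se <= 0] <- NA
    tt
  }

  obs_ind <- matrix(c(rep(1, na), rep(0, nb)), ncol = 1)
  t_obs <- as.numeric(t_stat_all(obs_ind))
  p_raw <- 2 * stats::pt(-abs(t_obs), df)

  perm_ind <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      g <- numeric(n); g[sample.int(n, na)] <- 1; g
    }, numeric(n))
  })
  good <- !is.na(t_obs)
  p_corr <- rep(NA_real_, length(t_obs))
  max_t <- rep(-Inf, n_perm)
  if (any(good)) {
    t_perm <- abs(t_stat_all(perm_ind)[good, , drop = FALSE])
    t_perm[is.na(t_perm)] <- -Inf   # degenerate under a permuted labeling
    max_t <- apply(t_perm, 2, max)
    cmp <- vapply(abs(t_obs[good]), function(tv) sum(max_t >= tv),
                  numeric(1))
    p_corr[good] <- (1 + cmp) / (n_perm + 1)
  }
  # corrected p can never undercut raw p
  p_corr <- pmax(p_corr, p_raw)

  to_arr <- function(v) {
    a <- array(NA_real_, dim(grid)); a[idx] <- v; a
  }
  structure(list(statistic = to_arr(t_obs), p_raw = to_arr(p_raw),
                 p_corrected = to_arr(p_corr), mask = analysis_mask,
                 affine = grid$affine, n_a = na, n_b = nb, df = df,
                 n_perm = n_perm, max_t = max_t,
                 method = "pooled t, max-T permutation FWE"),
            class = "nm_statmap")
}

#' @export
print.nm_statmap <- function(x, ...) {
  nsig <- sum(x$p_corrected < 0.05 & x$statistic > 0, na.rm = TRUE)
  cat(sprintf(
    "<nm_statmap> %s | %d mask voxels | %d perms | %d voxels with corrected p < 0.05 (A > B)\n",
    x$method, sum(x$mask), x$n_perm, nsig))
  invisible(x)
}

#' Extract N1/N2 ROIs from a thresholded statistic map
#'
#' Keeps voxels with `p_corrected < alpha` where the statistic indicates
#' signal loss in patients (statistic > 0 under the controls-minus-patients
#' convention), splits them at the template midsagittal plane, takes
#' 26-connected components per side, and labels the two largest components
#' by position: the posterolateral one is N1, the anteromedial one N2
#' (projection of the component centroid, relative to that side's SNpc
#' centroid, onto the posterolateral direction).
#'
#' @param stat_map an `nm_statmap`.
#' @param snpc_masks named list with `left_snpc` and `right_snpc` logical
#'   arrays (fixed template masks; supply ground-truth masks in phantom
#'   pipelines).
#' @param reference_mask logical array, the fixed reference region carried
#'   into the ROI set.
#' @param alpha corrected-p threshold (default 0.05).
#' @return object of class `nm_roiset`: `labels` (named list of logical
#'   arrays `left_n1`, `left_n2`, `right_n1`, `right_n2`, `left_snpc`,
#'   `right_snpc`, `reference`), `volumes_mm3` tibble, `affine`, and a
#'   `status` character vector of warnings raised.
#' @export
extract_rois <- function(stat_map, snpc_masks, reference_mask,
                         alpha = 0.05) {
  sig <- stat_map$p_corrected < alpha & stat_map$statistic > 0
  sig[is.na(sig)] <- FALSE
  if (!any(sig))
    stop("no significant voxels at the requested alpha", call. = FALSE)
  d <- dim(sig)
  mid <- (d[1] - 1) / 2   # midsagittal plane in voxel index space
  status <- character(0)
  labels <- list()
  vs <- sqrt(colSums(stat_map$affine[1:3, 1:3]^2))
  vv <- prod(vs)
  # Label components on the full map, then assign each component to a side
  # by its centroid relative to the midsagittal plane: a component touching
  # the plane goes to the side its centroid falls on.
  comp_all <- connected_components(sig, connectivity = 26)
  comp_side <- vapply(seq_len(max(comp_all)), function(k) {
    cx <- mean(arrayInd(which(comp_all == k), d)[, 1] - 1)
    if (cx < mid) "left" else "right"
  }, character(1))
  for (side in c("left", "right")) {
    comp <- array(0L, d)
    ks <- which(comp_side == side)
    for (j in seq_along(ks)) comp[comp_all == ks[j]] <- j
    ncomp <- length(ks)
    if (ncomp == 0) {
      status <- c(status,
                  sprintf("no significant component on the %s side", side))
      next
    }
    sn_cent <- mask_centroid_world(snpc_masks[[paste0(side, "_snpc")]],
                                   stat_map$affine)
    lat_sign <- if (side == "left") -1 else 1
    # posterolateral unit direction: lateral (away from midline) and
    # posterior (-y), in world RAS+ mm
    u <- c(lat_sign, -1, 0) / sqrt(2)
    take <- order(tabulate(comp[comp > 0]), decreasing = TRUE)[1:min(2, ncomp)]
    cent_proj <- vapply(take, function(k) {
      sum((mask_centroid_world(comp == k, stat_map$affine) - sn_cent) * u)
    }, numeric(1))
    if (length(take) == 1) {
      labels[[paste0(side, "_n1")]] <- comp == take[1]
      status <- c(status, sprintf(
        "only one significant component on the %s side: N1 assigned, N2 missing",
        side))
    } else {
      n1_k <- take[which.max(cent_proj)]
      n2_k <- take[which.min(cent_proj)]
      labels[[paste0(side, "_n1")]] <- comp == n1_k
      labels[[paste0(side, "_n2")]] <- comp == n2_k
      if (ncomp > 2)
        status <- c(status, sprintf(
          "%d extra significant component(s) on the %s side ignored",
          ncomp - 2, side))
    }
  }
  if (!length(labels))
    stop("no significant components on either side", call. = FALSE)
  for (w in status) warning(w, call. = FALSE)
  labels$left_snpc <- snpc_masks$left_snpc
  labels$right_snpc <- snpc_masks$right_snpc
  labels$reference <- reference_mask
  vols <- tibble::tibble(
    label = names(labels),
    n_voxels = unname(vapply(labels, sum, numeric(1))),
    volume_mm3 = unname(vapply(labels, function(m) sum(m) * vv,
                               numeric(1))))
  for (side in c("left", "right")) {
    v1 <- vols$volume_mm3[vols$label == paste0(side, "_n1")]
    v2 <- vols$volume_mm3[vols$label == paste0(side, "_n2")]
    if (length(v1) && length(v2) && v1 <= v2)
      warning(sprintf("%s N1 volume not larger than N2 volume", side),
              call. = FALSE)
  }
  structure(list(labels = labels, volumes_mm3 = vols,
                 affine = stat_map$affine, alpha = alpha, status = status),
            class = "nm_roiset")
}

#' @export
print.nm_roiset <- function(x, ...) {
  cat(sprintf("<nm_roiset> alpha = %g\n", x$alpha))
  print(x$volumes_mm3)
  invisible(x)
}

#' Write a statistic map / ROI set as NIfTI with a JSON legend
#'
#' @param stat_map an `nm_statmap`.
#' @param prefix output path prefix (files `<prefix>_t.nii.gz`,
#'   `<prefix>_praw.nii.gz`, `<prefix>_pcorr.nii.gz`).
#' @return invisibly, the paths written.
#' @export
write_statmap <- function(stat_map, prefix) {
  paths <- c(t = paste0(prefix, "_t.nii.gz"),
             p_raw = paste0(prefix, "_praw.nii.gz"),
             p_corr = paste0(prefix, "_pcorr.nii.gz"))
  wv <- function(a, p) {
    a[is.na(a)] <- 0
    write_volume(nm_volume(a, affine = stat_map$affine), p)
  }
  wv(stat_map$statistic, paths["t"])
  wv(stat_map$p_raw, paths["p_raw"])
  wv(stat_map$p_corrected, paths["p_corr"])
  invisible(paths)
}

#' @rdname write_statmap
#' @param rois an `nm_roiset`.
#' @export
write_roiset <- function(rois, prefix) {
  lab <- array(0L, dim(rois$labels[[1]]))
  legend <- list()
  for (i in seq_along(rois$labels)) {
    lab[rois$labels[[i]]] <- i
    legend[[names(rois$labels)[i]]] <- list(
      value = i,
      volume_mm3 = rois$volumes_mm3$volume_mm3[
        rois$volumes_mm3$label == names(rois$labels)[i]])
  }
  nii <- paste0(prefix, "_labels.nii.gz")
  js <- paste0(prefix, "_labels.json")
  write_volume(nm_volume(lab + 0, affine = rois$affine), nii)
  jsonlite::write_json(legend, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(labels = nii, legend = js))
}
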