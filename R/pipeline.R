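#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end analysis: where the cohort lives
#' and results go, the phantom generator settings, template-building,
#' voxelwise-testing and statistics options. Serializes losslessly to JSON;
#' unknown keys are rejected on read so typos cannot silently change a run.
#'
#' @param work_dir results directory.
#' @param cohort_dir directory holding `cohort.csv`, subject NIfTI files
#'   and the ground-truth label volume (as written by [cmd_simulate()]).
#' @param phantom a [phantom_config()] (or plain list of its fields).
#' @param template list: `n_iter`, `register`, `reference`.
#' @param voxelwise list: `alpha`, `n_perm`, `seed`, `margin_voxels`.
#' @param stats list: `regions`, `ci_method`.
#' @param roi list: `fallback_to_truth` — when the voxelwise map has no
#'   significant component, fall back to the ground-truth N1/N2 masks so
#'   minimal cohorts still produce a complete results bundle (the fallback
#'   is recorded in the manifest).
#' @return nested list of class `nm_pipeline_config`.
#' @export
pipeline_config <- function(work_dir = "results",
                            cohort_dir = "cohort",
                            phantom = phantom_config(),
                            template = list(n_iter = 2, register = TRUE,
                                            reference = "median"),
                            voxelwise = list(alpha = 0.05, n_perm = 1000,
                                             seed = 1L, margin_voxels = 2),
                            stats = list(regions = cr_regions(),
                                         ci_method = "delong"),
                            roi = list(fallback_to_truth = TRUE)) {
  defaults <- list(n_iter = 2, register = TRUE, reference = "median")
  template <- utils::modifyList(defaults, template)
  voxelwise <- utils::modifyList(
    list(alpha = 0.05, n_perm = 1000, seed = 1L, margin_voxels = 2),
    voxelwise)
  stats <- utils::modifyList(
    list(regions = cr_regions(), ci_method = "delong"), stats)
  roi <- utils::modifyList(list(fallback_to_truth = TRUE), roi)
  if (!is.numeric(voxelwise$seed) || length(voxelwise$seed) != 1)
    stop("voxelwise$seed must be a single number", call. = FALSE)
  if (!inherits(phantom, "nm_phantom_config"))
    phantom <- do.call(phantom_config, phantom)
  structure(list(paths = list(work_dir = work_dir,
                              cohort_dir = cohort_dir),
                 phantom = phantom, template = template,
                 voxelwise = voxelwise, stats = stats, roi = roi),
            class = "nm_pipeline_config")
}

#' Read / write a pipeline configuration as JSON
#' @param config an `nm_pipeline_config`.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  obj <- lapply(unclass(config), function(x) if (is.list(x)) unclass(x)
                else x)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ref <- unclass(pipeline_config())
  unknown_top <- setdiff(names(obj), names(ref))
  if (length(unknown_top))
    stop("unknown config keys: ", paste(unknown_top, collapse = ", "),
         call. = FALSE)
  for (sec in names(obj)) {
    bad <- setdiff(names(obj[[sec]]),
                   names(if (sec == "phantom") unclass(phantom_config())
                         else ref[[sec]]))
    if (length(bad))
      stop(sprintf("unknown config keys in %s: %s", sec,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  pipeline_config(work_dir = obj$paths$work_dir,
                  cohort_dir = obj$paths$cohort_dir,
                  phantom = obj$phantom,
                  template = as.list(obj$template),
                  voxelwise = as.list(obj$voxelwise),
                  stats = as.list(obj$stats),
                  roi = as.list(obj$roi))
}

#' Simulate a cohort to disk (pipeline stage)
#'
#' Thin wrapper over [write_cohort()] that also logs the seed and config
#' hash into `simulate_manifest.json`.
#'
#' @param config an `nm_pipeline_config`.
#' @param aligned passed to [write_cohort()].
#' @return invisibly, the cohort paths.
#' @export
cmd_simulate <- function(config, aligned = FALSE) {
  t0 <- Sys.time()
  paths <- write_cohort(config$phantom, config$paths$cohort_dir,
                        aligned = aligned)
  manifest <- list(stage = "simulate",
                   seed = config$phantom$seed,
                   aligned = aligned,
                   config_hash = rlang::hash(unclass(config)),
                   package_version =
                     as.character(utils::packageVersion("nigramap")),
                   elapsed_s = as.numeric(Sys.time() - t0, units = "secs"))
  jsonlite::write_json(manifest,
                       file.path(config$paths$cohort_dir,
                                 "simulate_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(paths)
}

read_cohort_dir <- function(cohort_dir) {
  csv <- file.path(cohort_dir, "cohort.csv")
  if (!file.exists(csv))
    stop(sprintf("cohort CSV not found at %s", csv), call. = FALSE)
  cohort <- readr::read_csv(csv, show_col_types = FALSE, progress = FALSE)
  volumes <- stats::setNames(
    lapply(file.path(cohort_dir, cohort$image_path), read_volume),
    cohort$subject_id)
  lab_path <- file.path(cohort_dir, "ground_truth_labels.nii.gz")
  gt_path <- file.path(cohort_dir, "ground_truth.json")
  masks <- NULL
  if (file.exists(lab_path) && file.exists(gt_path)) {
    lab <- read_volume(lab_path)
    legend <- jsonlite::read_json(gt_path,
                                  simplifyVector = TRUE)$label_legend
    masks <- lapply(legend, function(v) lab$data == v)
  }
  list(cohort = cohort, volumes = volumes, masks = masks)
}

#' Run the full template-based analysis pipeline
#'
#' Stages: preprocess (foreground strip + provisional intensity scaling) ->
#' template construction -> spatial normalization into template space ->
#' reference-based intensity normalization -> voxelwise group test ->
#' ROI extraction -> contrast-ratio table -> diagnostics. All outputs plus
#' a run manifest (stage timings, seeds, config hash) are written under
#' `config$paths$work_dir`. Stage failures abort with the stage name;
#' outputs written so far are kept.
#'
#' @param config an `nm_pipeline_config`.
#' @return invisibly, a list with the main result objects.
#' @export
cmd_run <- function(config) {
  wd <- config$paths$work_dir
  dir.create(wd, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = rlang::hash(unclass(config)),
                   voxelwise_seed = config$voxelwise$seed,
                   phantom_seed = config$phantom$seed,
                   package_version =
                     as.character(utils::packageVersion("nigramap")),
                   stages = list(), notes = character(0))
  add_note <- function(msg) manifest$notes <<- c(manifest$notes, msg)
  timer <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[name]] <<-
      round(as.numeric(Sys.time() - t0, units = "secs"), 3)
    out
  }

  inp <- timer("load_cohort", read_cohort_dir(config$paths$cohort_dir))
  cohort <- inp$cohort
  masks <- inp$masks
  if (is.null(masks))
    stop("stage 'load_cohort' failed: ground-truth label volume required ",
         "for the SNpc and reference masks", call. = FALSE)

  pre <- timer("preprocess", {
    lapply(inp$volumes, function(v) {
      fg <- strip_background(v)
      normalize_intensity(v, fg)   # provisional scaling for registration
    })
  })

  tmpl <- timer("template", {
    build_template(pre, n_iter = config$template$n_iter,
                   initial_reference = config$template$reference,
                   register = isTRUE(config$template$register))
  })

  warped <- timer("spatial_normalization", {
    if (isTRUE(config$template$register)) {
      stats::setNames(lapply(names(pre), function(sid)
        resample_volume(pre[[sid]], tmpl$transforms[[sid]],
                        target = tmpl$template, fill = NA_real_)),
        names(pre))
    } else pre
  })

  normed <- timer("intensity_normalization", {
    lapply(warped, function(v) {
      v$data[is.na(v$data)] <- 0
      normalize_intensity(v, masks$reference)
    })
  })

  stat_map <- timer("voxelwise", {
    amask <- dilate_mask(masks$left_snpc | masks$right_snpc,
                         config$voxelwise$margin_voxels)
    hc_ids <- cohort$subject_id[cohort$group == "HC"]
    ipd_ids <- cohort$subject_id[cohort$group == "IPD"]
    voxelwise_test(normed[hc_ids], normed[ipd_ids], amask,
                   n_perm = config$voxelwise$n_perm,
                   seed = config$voxelwise$seed)
  })

  rois <- timer("roi_extraction", {
    r <- tryCatch(
      suppressWarnings(extract_rois(stat_map, masks, masks$reference,
                                    alpha = config$voxelwise$alpha)),
      error = function(e) e)
    need <- c("left_n1", "left_n2", "right_n1", "right_n2")
    incomplete <- inherits(r, "error") ||
      length(setdiff(need, names(r$labels))) > 0
    if (incomplete && isTRUE(config$roi$fallback_to_truth)) {
      add_note("roi_extraction: voxelwise map incomplete; ground-truth N1/N2 masks used")
      vv <- prod(voxel_size(tmpl$template))
      labs <- masks[c("left_n1", "left_n2", "right_n1", "right_n2",
                      "left_snpc", "right_snpc", "reference")]
      structure(list(
        labels = labs,
        volumes_mm3 = tibble::tibble(
          label = names(labs),
          n_voxels = unname(vapply(labs, sum, numeric(1))),
          volume_mm3 = unname(vapply(labs, function(m) sum(m) * vv,
                                     numeric(1)))),
        affine = tmpl$template$affine, alpha = config$voxelwise$alpha,
        status = "ground-truth fallback"), class = "nm_roiset")
    } else if (inherits(r, "error")) {
      stop(conditionMessage(r), call. = FALSE)
    } else r
  })

  cr_table <- timer("contrast_ratios",
                    build_cr_table(cohort, normed, rois))

  diag_res <- timer("diagnostics", {
    res <- list()
    regions <- config$stats$regions
    n_min <- min(table(cohort$group))
    if (n_min >= 3) {
      res$comparisons <- compare_groups(cr_table, regions)
    } else {
      add_note("diagnostics: <3 subjects per group; group comparisons skipped")
      res$comparisons <- NULL
    }
    res$roc <- lapply(stats::setNames(regions, regions), function(rg)
      suppressWarnings(roc_analysis(cr_table, rg)))
    res$roc_pairs <- if (length(regions) >= 2)
      compare_rocs(cr_table, regions) else NULL
    res$loocv <- dplyr::bind_rows(lapply(regions, function(rg)
      suppressWarnings(loocv(cr_table, rg))))
    res$laterality <- tryCatch(laterality_concordance(cohort, cr_table),
                               error = function(e) {
      add_note(paste("diagnostics: laterality skipped:", conditionMessage(e)))
      NULL
    })
    res
  })

  timer("write_outputs", {
    write_volume(tmpl$template, file.path(wd, "template.nii.gz"))
    write_rigid_json(tmpl$transforms, file.path(wd, "transforms.json"))
    write_statmap(stat_map, file.path(wd, "statmap"))
    write_roiset(rois, file.path(wd, "rois"))
    write_cr_table(cr_table, file.path(wd, "cr_table.csv"))
    if (!is.null(diag_res$comparisons))
      readr::write_csv(diag_res$comparisons,
                       file.path(wd, "comparisons.csv"))
    roc_sum <- dplyr::bind_rows(lapply(diag_res$roc, glance))
    readr::write_csv(roc_sum, file.path(wd, "roc.csv"))
    readr::write_csv(diag_res$loocv, file.path(wd, "loocv.csv"))
    if (!is.null(diag_res$roc_pairs))
      utils::write.csv(diag_res$roc_pairs$p_matrix,
                       file.path(wd, "roc_pairwise_p.csv"))
    results <- list(
      aucs = lapply(diag_res$roc, function(r)
        list(auc = r$auc, ci = r$ci, sensitivity = r$sensitivity,
             specificity = r$specificity, threshold = r$threshold)),
      loocv = diag_res$loocv,
      laterality = if (!is.null(diag_res$laterality))
        list(fisher_p = diag_res$laterality$fisher_p,
             n_concordant = diag_res$laterality$n_concordant,
             n_determinate = diag_res$laterality$n_determinate,
             table = as.vector(diag_res$laterality$table)),
      roi_volumes_mm3 = rois$volumes_mm3)
    jsonlite::write_json(results, file.path(wd, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  jsonlite::write_json(manifest, file.path(wd, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(template = tmpl, stat_map = stat_map, rois = rois,
                 cr_table = cr_table, diagnostics = diag_res,
                 manifest = manifest))
}

#' Render a Markdown summary of a results bundle
#'
#' @param results_dir directory written by [cmd_run()].
#' @param path output Markdown path (default `report.md` inside
#'   `results_dir`).
#' @return invisibly, the report path.
#' @export
cmd_report <- function(results_dir, path = file.path(results_dir,
                                                     "report.md")) {
  need <- c("cr_table.csv", "roc.csv", "loocv.csv", "results.json",
            "manifest.json")
  missing <- need[!file.exists(file.path(results_dir, need))]
  if (length(missing))
    stop("results bundle incomplete; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  roc <- readr::read_csv(file.path(results_dir, "roc.csv"),
                         show_col_types = FALSE, progress = FALSE)
  cv <- readr::read_csv(file.path(results_dir, "loocv.csv"),
                        show_col_types = FALSE, progress = FALSE)
  res <- jsonlite::read_json(file.path(results_dir, "results.json"),
                             simplifyVector = TRUE)
  cr <- read_cr_table(file.path(results_dir, "cr_table.csv"))
  lines <- c("# Template-based contrast-ratio analysis report", "",
             sprintf("Subjects: %d (%s)", nrow(cr),
                     paste(sprintf("%s n=%d", names(table(cr$group)),
                                   as.integer(table(cr$group))),
                           collapse = ", ")), "")
  comp_path <- file.path(results_dir, "comparisons.csv")
  if (file.exists(comp_path)) {
    comp <- readr::read_csv(comp_path, show_col_types = FALSE,
                            progress = FALSE)
    lines <- c(lines, "## Group comparisons", "",
               "| region | test | statistic | p (adjusted) | IPD | HC |",
               "|---|---|---|---|---|---|",
               sprintf("| %s | %s | %.4g | %.4g | %s | %s |", comp$region,
                       comp$test, comp$statistic, comp$p_adjusted,
                       comp$summary_ipd, comp$summary_hc), "")
  }
  lines <- c(lines, "## Diagnostic performance", "",
             "| region | AUC | 95% CI | sens | spec | CV sens | CV spec |",
             "|---|---|---|---|---|---|---|",
             sprintf("| %s | %.3f | %.3f–%.3f | %.1f%% | %.1f%% | %.1f%% | %.1f%% |",
                     roc$region, roc$auc, roc$ci_low, roc$ci_high,
                     100 * roc$sensitivity, 100 * roc$specificity,
                     100 * cv$cv_sensitivity[match(roc$region, cv$region)],
                     100 * cv$cv_specificity[match(roc$region, cv$region)]),
             "")
  pw_path <- file.path(results_dir, "roc_pairwise_p.csv")
  if (file.exists(pw_path)) {
    pw <- utils::read.csv(pw_path, row.names = 1, check.names = FALSE)
    lines <- c(lines, "## Pairwise AUC comparisons (adjusted p)", "",
               paste0("| | ", paste(colnames(pw), collapse = " | "), " |"),
               paste0("|", paste(rep("---", ncol(pw) + 1), collapse = "|"),
                      "|"),
               vapply(seq_len(nrow(pw)), function(i)
                 paste0("| ", rownames(pw)[i], " | ",
                        paste(sprintf("%.3g", as.numeric(pw[i, ])),
                              collapse = " | "), " |"), character(1)), "")
  }
  if (!is.null(res$laterality))
    lines <- c(lines, "## Laterality concordance", "",
               sprintf("%d of %d determinate patients concordant; Fisher exact p = %.4g",
                       res$laterality$n_concordant,
                       res$laterality$n_determinate,
                       res$laterality$fisher_p), "")
  writeLines(lines, path)
  invisible(path)
}
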