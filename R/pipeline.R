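#' Pipeline configuration
#'
#' Validated parameter bundle for [run_pipeline()]. Unknown keys are
#' rejected so that typos never silently fall back to defaults, and a
#' config round-trips losslessly through JSON.
#'
#' @param cohort Named list of [cohort_spec()] arguments (plus optional
#'   `grid_shape`, `voxel_spacing`, `noise_sd_hu`, `noise_sd_suv` shortcuts
#'   applied to the phantom templates).
#' @param ct Named list: `radii_mm`, `roi_shape`, `stride`,
#'   `interpretation`, `manual` (logical; the ROI sweep is the slow step).
#' @param pet Named list: `erosion_mm`, `target_stat`, `gap_score`.
#' @param panel Data.frame (or list coercible to one) with `var1`, `var2`,
#'   `test` columns for [run_panel()]; `NULL` for the default panel.
#' @param alpha Significance level.
#' @param seed Integer; overrides the cohort seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = list(), ct = list(), pet = list(),
                            panel = NULL, alpha = 0.05, seed = 1L) {
  chk <- function(block, allowed, name) {
    bad <- setdiff(names(block), allowed)
    if (length(bad))
      stop(sprintf("unknown %s config keys: %s", name,
                   paste(bad, collapse = ", ")), call. = FALSE)
    block
  }
  cohort <- chk(cohort, c(names(formals(cohort_spec)), "grid_shape",
                          "voxel_spacing", "noise_sd_hu", "noise_sd_suv"),
                "cohort")
  ct <- chk(ct, c("radii_mm", "roi_shape", "stride", "interpretation",
                  "manual"), "ct")
  pet <- chk(pet, c("erosion_mm", "target_stat", "gap_score"), "pet")
  if (!is.null(panel)) {
    panel <- as.data.frame(panel, stringsAsFactors = FALSE)
    if (!all(c("var1", "var2", "test") %in% names(panel)))
      stop("panel must have var1, var2, test columns", call. = FALSE)
  }
  structure(list(cohort = cohort, ct = ct, pet = pet, panel = panel,
                 alpha = alpha, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON file written by [write_pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(pipeline_config, x)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

default_panel <- function() {
  data.frame(
    var1 = c("ctv", "cctv", "ctv", "cctv", "ctv", "cctv", "ctv", "cctv"),
    var2 = c("plasma_pct", "plasma_pct", "beta2m_mg_l", "beta2m_mg_l",
             "bm_suv_max", "bm_suv_max", "mtv_ml", "mtv_ml"),
    test = "spearman", stringsAsFactors = FALSE)
}

build_cohort_spec <- function(cfg, seed) {
  args <- cfg$cohort
  tweaks <- c("grid_shape", "voxel_spacing", "noise_sd_hu", "noise_sd_suv")
  ct_tmpl_args <- args[intersect(names(args),
                                 c("grid_shape", "voxel_spacing",
                                   "noise_sd_hu"))]
  ct_tmpl <- do.call(phantom_spec, ct_tmpl_args)
  pet_tmpl <- pet_spec(focal_lesion_suv = 6,
                       noise_sd_suv = args$noise_sd_suv %||% 0.05)
  args <- args[setdiff(names(args), tweaks)]
  args$ct_template <- args$ct_template %||% ct_tmpl
  args$pet_template <- args$pet_template %||% pet_tmpl
  args$seed <- seed
  do.call(cohort_spec, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# quantify one realized (patient, timepoint) scan pair into a table row
quantify_scan <- function(scan, ct_cfg, pet_cfg, alpha = 0.05) {
  wm <- medullary_working_mask(scan$ct, scan$masks$medullary_cavity,
                               scan$masks$epiphysis)
  cctv <- compute_cctv(scan$ct, wm,
                       interpretation = ct_cfg$interpretation %||% "density")
  ctv <- if (isTRUE(ct_cfg$manual %||% TRUE)) {
    manual_ctv(scan$ct, wm, radii_mm = ct_cfg$radii_mm %||% c(3, 4, 5, 6),
               roi_shape = ct_cfg$roi_shape %||% "disc",
               stride = ct_cfg$stride %||% 1L)$ctv
  } else NA_real_

  liver <- voi_stats(scan$pet, scan$pet_masks$liver)
  medi <- voi_stats(scan$pet, scan$pet_masks$mediastinum)
  bm <- voi_stats(scan$pet, resample_mask(wm, scan$pet))
  lesion_stats <- if (any(scan$pet_masks$lesions$data))
    voi_stats(scan$pet, scan$pet_masks$lesions) else NULL

  row <- scan$row
  n_focal <- if (is.null(lesion_stats)) 0L else row$n_focal
  rep <- impetus_report(
    bm_stats = bm, hottest_lesion_stats = lesion_stats,
    liver = liver, mediastinum = medi,
    n_focal = n_focal, n_lytic = row$n_lytic,
    pmd = row$pmd, emd = row$emd, fracture = row$fracture,
    target_stat = pet_cfg$target_stat %||% "suv_max",
    gap_score = pet_cfg$gap_score %||% 3L)

  skel_wm <- skeletal_working_mask(scan$pet_masks$skeleton,
                                   scan$pet_masks$skull,
                                   erosion_mm = pet_cfg$erosion_mm %||% 2)
  vol <- segment_and_quantify(scan$pet, skel_wm, mm_threshold(liver))

  data.frame(
    patient = row$patient, timepoint = row$timepoint, arm = row$arm,
    ctv = ctv, cctv = cctv$cctv,
    mm_volume_mm3 = cctv$mm_volume_mm3,
    cavity_volume_mm3 = cctv$cavity_volume_mm3,
    bm_suv_max = bm$suv_max, bm_suv_mean = bm$suv_mean,
    liver_suv_mean = liver$suv_mean, liver_suv_median = liver$suv_median,
    mediastinum_suv_mean = medi$suv_mean,
    lesion_suv_max = if (is.null(lesion_stats)) NA_real_ else
      lesion_stats$suv_max,
    ds_bone_marrow = rep$ds_bone_marrow,
    ds_hottest_lesion = if (is.null(rep$ds_hottest_lesion)) NA_integer_
      else rep$ds_hottest_lesion,
    f_category = rep$f_category, l_category = rep$l_category,
    n_focal = row$n_focal, n_lytic = row$n_lytic,
    pmd = row$pmd, emd = row$emd, fracture = row$fracture,
    mtv_ml = vol$mtv_ml, tlg_g = vol$tlg_g,
    plasma_pct = row$plasma_pct, beta2m_mg_l = row$beta2m_mg_l,
    mrd = row$mrd, true_infiltration = row$true_infiltration,
    stringsAsFactors = FALSE)
}

#' Run the end-to-end phantom pipeline
#'
#' Generates (or streams) a phantom cohort, quantifies every scan (CT
#' working mask, CTv, cCTv, SUV VOIs, IMPeTUs report, MTV/TLG), runs the
#' baseline-vs-follow-up paired comparisons and the association panel, and
#' writes `cohort.csv`, `paired.csv`, `panel.csv` and a provenance-stamped
#' `config.json` to `out_dir`. Identical config and seed give byte-identical
#' CSVs.
#'
#' @param config A [pipeline_config()] (or path to its JSON form).
#' @param out_dir Output directory, created if needed; `NULL` skips writing.
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list: `cohort` (per-scan results data.frame),
#'   `paired` (signed-rank comparisons for cctv/ctv/mtv/tlg), `panel`
#'   (association results), `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config"))
    stop("`config` must be a pipeline_config or a path to one",
         call. = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  cspec <- build_cohort_spec(config, config$seed)
  say("pipeline: generating cohort of %d patients (seed %d)",
      cspec$n_patients, cspec$seed)
  cohort <- make_cohort(cspec)

  rows <- lapply(seq_len(nrow(cohort$truth)), function(i) {
    scan <- realize_row(cohort, i)
    quantify_scan(scan, config$ct, config$pet, config$alpha)
  })
  tab <- do.call(rbind, rows)
  say("pipeline: quantified %d scans", nrow(tab))

  base <- tab[tab$timepoint == "baseline", ]
  fu <- tab[tab$timepoint == "followup", ]
  fu <- fu[match(base$patient, fu$patient), ]
  paired <- do.call(rbind, lapply(
    c("cctv", "ctv", "mtv_ml", "tlg_g", "bm_suv_max"), function(v) {
      if (all(is.na(base[[v]]))) return(NULL)
      res <- paired_compare(base[[v]], fu[[v]])
      cbind(data.frame(variable = v, stringsAsFactors = FALSE), res)
    }))

  panel_spec <- config$panel %||% default_panel()
  panel <- run_panel(base, panel_spec, alpha = config$alpha)

  out <- list(cohort = tab, paired = paired, panel = panel, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wcsv <- function(df, f) utils::write.csv(
      df, file.path(out_dir, f), row.names = FALSE)
    wcsv(tab, "cohort.csv"); wcsv(paired, "paired.csv")
    wcsv(panel, "panel.csv")
    stamp <- c(unclass(config),
               list(package_version =
                      as.character(utils::packageVersion("marrowquant"))))
    jsonlite::write_json(stamp, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    say("pipeline: results written to %s", out_dir)
  }
  invisible(out)
}
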