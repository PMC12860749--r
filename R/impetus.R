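#' Five-point Deauville score
#'
#' Grades target uptake against the mediastinal blood pool (M) and liver (L)
#' references:
#' \itemize{
#'   \item DS1 — no uptake: target at or below the background-VOI mean when
#'     a background VOI is supplied, else exactly zero;
#'   \item DS2 — at or below mediastinal blood-pool uptake;
#'   \item DS3 — above mediastinum, up to liver + 10%;
#'   \item DS4 — above liver + 10%, up to twice liver;
#'   \item DS5 — above twice liver uptake.
#' }
#' The published wording leaves (L, 1.1 L\] unassigned (DS3 stops at the
#' liver, DS4 starts above liver + 10%); by the conservative convention used
#' here that gap scores DS3, i.e. DS4 requires exceeding 1.1 L (override
#' with `gap_score = 4L`). The comparison statistic is target SUVmax against
#' reference SUVmean by default, as in common reading practice.
#'
#' @param target `suv_stats` for the graded region, or a bare numeric SUV.
#' @param liver,mediastinum Reference `suv_stats` (or bare numerics, taken
#'   as SUVmean).
#' @param background Optional background `suv_stats`/numeric for the DS1
#'   "no uptake" cutoff.
#' @param target_stat Which target statistic to compare: "suv_max"
#'   (default), "suv_mean" or "suv_median".
#' @param gap_score Score assigned on (L, 1.1 L\]: 3 (default) or 4.
#' @return Integer Deauville score(s) in 1..5. Bare numeric inputs are
#'   vectorized (recycled to a common length).
#' @export
deauville <- function(target, liver, mediastinum, background = NULL,
                      target_stat = c("suv_max", "suv_mean", "suv_median"),
                      gap_score = 3L) {
  target_stat <- match.arg(target_stat)
  pick <- function(x, stat) {
    if (inherits(x, "suv_stats")) x[[stat]]
    else if (is.numeric(x) && length(x) >= 1L && all(is.finite(x)) &&
             all(x >= 0)) x
    else stop("references must be suv_stats or nonnegative numbers",
              call. = FALSE)
  }
  t <- pick(target, target_stat)
  l <- pick(liver, "suv_mean")
  m <- pick(mediastinum, "suv_mean")
  if (!gap_score %in% c(3L, 4L))
    stop("gap_score must be 3 or 4", call. = FALSE)
  if (any(l < m))
    warning("liver reference below mediastinal blood pool; check VOIs",
            call. = FALSE)
  b <- if (is.null(background)) NULL else pick(background, "suv_mean")

  no_uptake <- if (is.null(b)) t == 0 else t <= b
  ds <- ifelse(no_uptake, 1L,
        ifelse(t <= m, 2L,
        ifelse(t <= l, 3L,
        ifelse(t <= 1.1 * l, gap_score,
        ifelse(t <= 2 * l, 4L, 5L)))))
  as.integer(ds)
}

#' Focal-lesion (Fx) and lytic-lesion (Lx) categories
#'
#' Band a lesion count into the four IMPeTUs categories: x1 for no lesions,
#' x2 for 1-3, x3 for 4-10, x4 for more than 10.
#'
#' @param n_focal,n_lytic Nonnegative integer lesion count.
#' @return Ordered factor `F1`..`F4` (resp. `L1`..`L4`).
#' @export
f_category <- function(n_focal) lesion_band(n_focal, "F")

#' @rdname f_category
#' @export
l_category <- function(n_lytic) lesion_band(n_lytic, "L")

lesion_band <- function(n, prefix) {
  if (length(n) != 1L || !is.finite(n) || n < 0 || n != round(n))
    stop("lesion count must be a single nonnegative integer", call. = FALSE)
  band <- if (n == 0) 1L else if (n <= 3) 2L else if (n <= 10) 3L else 4L
  factor(paste0(prefix, band),
         levels = paste0(prefix, 1:4), ordered = TRUE)
}

#' Assemble a structured IMPeTUs report
#'
#' Combines the Deauville score of diffuse bone-marrow uptake (lower lumbar
#' spine VOI), the score of the hottest focal lesion (absent when there are
#' no focal lesions), the Fx/Lx lesion-count categories and the
#' paramedullary-disease, extramedullary-disease and fracture flags.
#'
#' @param bm_stats `suv_stats` of the reference bone-marrow VOI.
#' @param hottest_lesion_stats `suv_stats` of the hottest focal lesion, or
#'   `NULL` when `n_focal == 0`.
#' @param liver,mediastinum,background Reference stats, see [deauville()].
#' @param n_focal,n_lytic Lesion counts.
#' @param pmd,emd,fracture Logical flags.
#' @param ... Passed to [deauville()] (`target_stat`, `gap_score`).
#' @return An `impetus_report` list.
#' @export
impetus_report <- function(bm_stats, hottest_lesion_stats = NULL,
                           liver, mediastinum, background = NULL,
                           n_focal = 0L, n_lytic = 0L,
                           pmd = FALSE, emd = FALSE, fracture = FALSE,
                           ...) {
  if (n_focal == 0L && !is.null(hottest_lesion_stats))
    stop("inconsistent inputs: lesion stats supplied with n_focal = 0",
         call. = FALSE)
  if (n_focal > 0L && is.null(hottest_lesion_stats))
    stop("inconsistent inputs: n_focal > 0 but no hottest-lesion stats",
         call. = FALSE)
  for (flag in list(pmd, emd, fracture))
    if (!is.logical(flag) || length(flag) != 1L || is.na(flag))
      stop("pmd/emd/fracture must be single TRUE/FALSE flags", call. = FALSE)
  rep <- list(
    ds_bone_marrow = deauville(bm_stats, liver, mediastinum, background,
                               ...),
    ds_hottest_lesion = if (n_focal > 0L)
      deauville(hottest_lesion_stats, liver, mediastinum, background, ...)
    else NULL,
    f_category = as.character(f_category(n_focal)),
    l_category = as.character(l_category(n_lytic)),
    n_focal = as.integer(n_focal), n_lytic = as.integer(n_lytic),
    pmd = pmd, emd = emd, fracture = fracture)
  class(rep) <- "impetus_report"
  rep
}

#' @export
print.impetus_report <- function(x, ...) {
  cat(sprintf(
    "IMPeTUs: BM DS%d  lesion %s  %s %s  PMD=%s EMD=%s fracture=%s\n",
    x$ds_bone_marrow,
    if (is.null(x$ds_hottest_lesion)) "-" else
      paste0("DS", x$ds_hottest_lesion),
    x$f_category, x$l_category, x$pmd, x$emd, x$fracture))
  invisible(x)
}

#' Serialize / restore an IMPeTUs report as JSON
#'
#' Round-trips losslessly: `impetus_from_json(impetus_to_json(r))` equals
#' `r`. The schema is versioned for forward compatibility.
#'
#' @param report An `impetus_report`.
#' @param path Optional file to write to / read from.
#' @return `impetus_to_json`: JSON string (invisibly, if written to file).
#'   `impetus_from_json`: an `impetus_report`.
#' @export
impetus_to_json <- function(report, path = NULL) {
  payload <- c(list(schema = "impetus_report/1"), unclass(report))
  payload$ds_hottest_lesion <- if (is.null(report$ds_hottest_lesion))
    NA_integer_ else report$ds_hottest_lesion
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null",
                         na = "null", digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname impetus_to_json
#' @param json JSON string (ignored when `path` given).
#' @export
impetus_from_json <- function(json = NULL, path = NULL) {
  x <- jsonlite::fromJSON(if (!is.null(path)) path else json)
  if (!identical(x$schema, "impetus_report/1"))
    stop("not an impetus_report/1 document", call. = FALSE)
  rep <- list(
    ds_bone_marrow = as.integer(x$ds_bone_marrow),
    ds_hottest_lesion = if (is.null(x$ds_hottest_lesion) ||
                            is.na(x$ds_hottest_lesion)) NULL else
      as.integer(x$ds_hottest_lesion),
    f_category = x$f_category, l_category = x$l_category,
    n_focal = as.integer(x$n_focal), n_lytic = as.integer(x$n_lytic),
    pmd = x$pmd, emd = x$emd, fracture = x$fracture)
  class(rep) <- "impetus_report"
  rep
}
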