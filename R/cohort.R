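#' Synthetic cohort specification
#'
#' Describes a paired baseline/follow-up phantom cohort with planted ground
#' truth: baseline infiltration fractions drawn from a Beta distribution,
#' a multiplicative treatment effect applied at follow-up, monotone links
#' from infiltration to the clinical covariates (plasma-cell infiltration %
#' via a square-root link, beta2-microglobulin via a linear link), a logistic
#' model for MRD negativity after therapy, and per-patient lesion counts and
#' disease flags. Defaults emulate a newly diagnosed transplant-eligible
#' myeloma cohort: median baseline infiltration ~0.30 (giving ~55% plasma
#' cells and ~2.8 mg/L beta2-microglobulin at the median), a strong induction
#' effect (0.8), and ~40% MRD negativity at follow-up.
#'
#' @param n_patients Number of patients (>= 2).
#' @param ct_template,pet_template [phantom_spec()] / [pet_spec()] templates;
#'   per-patient infiltration, lesion counts and seeds are filled in.
#' @param infiltration_alpha,infiltration_beta Beta parameters of the
#'   baseline infiltration distribution (defaults mean 0.30).
#' @param treatment_effect Multiplicative reduction of infiltration and
#'   focal-lesion SUV at follow-up, in [0, 1].
#' @param plasma_noise_sd,b2m_noise_sd Gaussian noise on the covariate links
#'   (percentage points / mg/L).
#' @param mrd_intercept,mrd_slope Logistic model:
#'   `P(MRD-negative) = plogis(mrd_intercept - mrd_slope * f_followup)`.
#' @param focal_mu,focal_size Negative-binomial model of baseline focal
#'   lesion counts; follow-up counts are binomially thinned by
#'   `1 - treatment_effect`.
#' @param lytic_mu,lytic_size Negative-binomial model of lytic lesion counts
#'   (unchanged by induction).
#' @param seed Integer seed; fully determines the cohort.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 40L,
                        ct_template = phantom_spec(),
                        pet_template = pet_spec(focal_lesion_suv = 6,
                                                noise_sd_suv = 0.05),
                        infiltration_alpha = 3, infiltration_beta = 7,
                        treatment_effect = 0.8,
                        plasma_noise_sd = 8,
                        b2m_noise_sd = 0.6,
                        mrd_intercept = 1.5, mrd_slope = 30,
                        focal_mu = 4, focal_size = 0.6,
                        lytic_mu = 8, lytic_size = 0.4,
                        seed = 1L) {
  spec <- list(n_patients = as.integer(n_patients),
               ct_template = ct_template, pet_template = pet_template,
               infiltration_alpha = infiltration_alpha,
               infiltration_beta = infiltration_beta,
               treatment_effect = treatment_effect,
               plasma_noise_sd = plasma_noise_sd,
               b2m_noise_sd = b2m_noise_sd,
               mrd_intercept = mrd_intercept, mrd_slope = mrd_slope,
               focal_mu = focal_mu, focal_size = focal_size,
               lytic_mu = lytic_mu, lytic_size = lytic_size,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  if (spec$n_patients < 2L)
    stop("invalid cohort spec: n_patients must be >= 2", call. = FALSE)
  if (spec$treatment_effect < 0 || spec$treatment_effect > 1)
    stop("invalid cohort spec: treatment_effect must be in [0, 1]",
         call. = FALSE)
  if (spec$plasma_noise_sd < 0 || spec$b2m_noise_sd < 0)
    stop("invalid cohort spec: noise sds must be >= 0", call. = FALSE)
  validate_phantom_spec(spec$ct_template)
  spec
}

# monotone covariate links (noise-free): infiltration -> covariate
plasma_link <- function(f) 100 * sqrt(f)
b2m_link <- function(f) 0.9 + 6.3 * f

#' Generate a paired baseline/follow-up phantom cohort
#'
#' Draws per-patient ground truth (infiltration, covariates, lesion counts,
#' flags, MRD) and per-scan phantom specs under a single seed. Volumes are
#' generated on demand by [realize_patient()] so that large cohorts can be
#' processed in a streaming fashion; `materialize = TRUE` additionally
#' returns every phantom pair in memory (small cohorts only).
#'
#' @param spec A [cohort_spec()].
#' @param materialize If `TRUE`, include `$patients`, a list of realized
#'   phantom pairs per (patient, timepoint).
#' @return An `mm_cohort`: `$truth` (one row per patient per timepoint:
#'   ground truth, covariates, flags, per-scan seeds), `$specs` (per-row
#'   [phantom_spec()]/[pet_spec()] pairs) and `$spec` (the input).
#' @export
make_cohort <- function(spec, materialize = FALSE) {
  if (!inherits(spec, "cohort_spec")) stop("`spec` must be a cohort_spec",
                                           call. = FALSE)
  n <- spec$n_patients
  te <- spec$treatment_effect
  truth <- with_seed(spec$seed, {
    f_base <- clamp(stats::rbeta(n, spec$infiltration_alpha,
                                 spec$infiltration_beta), 0.02, 0.95)
    f_fu <- f_base * (1 - te)
    arm <- sample(rep(c("isatuximab", "control"), length.out = n))
    n_focal_base <- stats::rnbinom(n, mu = spec$focal_mu,
                                   size = spec$focal_size)
    n_focal_fu <- stats::rbinom(n, n_focal_base, 1 - te)
    n_lytic <- stats::rnbinom(n, mu = spec$lytic_mu, size = spec$lytic_size)
    fracture_base <- stats::runif(n) < 0.6
    fracture_fu <- fracture_base | stats::runif(n) < 0.15
    pmd_base <- stats::runif(n) < 0.32
    pmd_fu <- pmd_base & stats::runif(n) < 0.12
    emd_base <- stats::runif(n) < 0.04
    emd_fu <- emd_base
    p_mrd_neg <- stats::plogis(spec$mrd_intercept - spec$mrd_slope * f_fu)
    mrd_fu <- ifelse(stats::runif(n) < p_mrd_neg, "negative", "positive")

    cov_noise <- function(f, link, sd, lo, hi)
      clamp(link(f) + stats::rnorm(n, 0, sd), lo, hi)
    df <- function(tp, f, nf, frac, pmd, emd, mrd) data.frame(
      patient = seq_len(n), timepoint = tp, arm = arm,
      true_infiltration = f,
      plasma_pct = cov_noise(f, plasma_link, spec$plasma_noise_sd, 0, 100),
      beta2m_mg_l = cov_noise(f, b2m_link, spec$b2m_noise_sd, 0.1, Inf),
      n_focal = nf, n_lytic = n_lytic,
      fracture = frac, pmd = pmd, emd = emd, mrd = mrd,
      stringsAsFactors = FALSE)
    out <- rbind(df("baseline", f_base, n_focal_base, fracture_base,
                    pmd_base, emd_base, NA_character_),
                 df("followup", f_fu, n_focal_fu, fracture_fu,
                    pmd_fu, emd_fu, mrd_fu))
    out$ct_seed <- sample.int(.Machine$integer.max, 2L * n)
    out$pet_seed <- sample.int(.Machine$integer.max, 2L * n)
    out[order(out$patient, out$timepoint), ]
  })
  rownames(truth) <- NULL

  specs <- lapply(seq_len(nrow(truth)), function(i) {
    row <- truth[i, ]
    ct <- spec$ct_template
    ct$infiltration_fraction <- row$true_infiltration
    ct$seed <- row$ct_seed
    if (row$n_focal > 0L) {
      ct$infiltration_pattern <- "mixed"
      ct$n_focal_lesions <- row$n_focal
    } else ct$infiltration_pattern <- "diffuse"
    validate_phantom_spec(ct)
    pet <- spec$pet_template
    pet$seed <- row$pet_seed
    if (row$timepoint == "followup")
      pet$focal_lesion_suv <- pet$focal_lesion_suv * (1 - te)
    list(ct = ct, pet = pet)
  })

  cohort <- structure(list(spec = spec, truth = truth, specs = specs),
                      class = "mm_cohort")
  if (materialize)
    cohort$patients <- lapply(seq_len(nrow(truth)), function(i)
      realize_row(cohort, i))
  cohort
}

#' @export
print.mm_cohort <- function(x, ...) {
  cat(sprintf("<mm_cohort> %d patients x 2 timepoints (seed %d)\n",
              x$spec$n_patients, x$spec$seed))
  invisible(x)
}

realize_row <- function(cohort, i) {
  sp <- cohort$specs[[i]]
  ctp <- make_ct_phantom(sp$ct)
  petp <- make_pet_phantom(sp$pet, ctp$masks, ctp$truth)
  list(ct = ctp$ct, masks = ctp$masks, truth = ctp$truth,
       pet = petp$pet, pet_masks = petp$masks, row = cohort$truth[i, ])
}

#' Realize one phantom pair from a cohort
#'
#' @param cohort An `mm_cohort` from [make_cohort()].
#' @param patient Patient id (1-based).
#' @param timepoint "baseline" or "followup".
#' @return The realized pair: `ct`, `masks`, `truth`, `pet`, `masks` from the
#'   PET phantom merged in as `pet_masks`, and the cohort `row`.
#' @export
realize_patient <- function(cohort, patient,
                            timepoint = c("baseline", "followup")) {
  timepoint <- match.arg(timepoint)
  i <- which(cohort$truth$patient == patient &
               cohort$truth$timepoint == timepoint)
  if (length(i) != 1L)
    stop(sprintf("no cohort row for patient %s at %s", patient, timepoint),
         call. = FALSE)
  realize_row(cohort, i)
}
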