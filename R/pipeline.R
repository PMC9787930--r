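# End-to-end glue: volume preparation, KBF and classifier-input extraction
# for whole cohorts.

#' Prepare a patient's volumes for the ROI filter
#'
#' Resamples FLAIR and T1-w to 1 mm isotropic resolution, reorients both to
#' the sagittal standard, optionally rigidly registers T1-w onto FLAIR, and
#' applies the brain mask (an external mask is preferred; without one the
#' intensity-based fallback is computed from the FLAIR volume).
#'
#' @param flair,t1 [brain_volume]s.
#' @param brain optional [brain_mask] aligned with the *prepared* FLAIR
#'   volume; `NULL` computes [fallback_brain_mask].
#' @param register if `TRUE`, rigidly register T1-w to FLAIR before
#'   masking.
#' @return list with prepared `flair`, `t1` and `brain`.
#' @export
prepare_patient <- function(flair, t1, brain = NULL, register = FALSE) {
  fl <- reorient_to_sagittal(resample_isotropic(flair))
  t1p <- reorient_to_sagittal(resample_isotropic(t1))
  if (register) {
    tf <- register_rigid(t1p, fl)
    t1p <- apply_rigid(t1p, tf, out_dim = dim(fl$grid))
  }
  if (is.null(brain)) brain <- fallback_brain_mask(fl)
  if (!identical(dim(brain$grid), dim(fl$grid)))
    stop("brain mask shape does not match the prepared volumes")
  list(flair = apply_brain_mask(fl, brain),
       t1 = apply_brain_mask(t1p, brain),
       brain = brain)
}

#' Classifier input for one phantom or patient
#'
#' Runs preparation and the KBF stage and returns the cropped, normalized,
#' ROI-masked FLAIR input, either as a 3D array (`dims = 3`) or as the list
#' of 2D slices whose ROI is nonempty (`dims = 2`; the slices a 2D
#' classifier scores and averages).
#'
#' @param flair,t1 [brain_volume]s.
#' @param brain optional [brain_mask].
#' @param params a [kbf_params].
#' @param dims 2 or 3.
#' @return input array (3D) or list of slice matrices (2D).
#' @export
classifier_input <- function(flair, t1, brain = NULL,
                             params = kbf_params(), dims = 3) {
  prep <- prepare_patient(flair, t1, brain)
  kb <- kbf_pipeline(prep$flair, prep$t1, prep$brain, params)
  if (dims == 3) return(kb$input$grid)
  keep <- which(apply(kb$roi_cropped != 0, 3, any))
  if (length(keep) == 0L) keep <- (dim(kb$input$grid)[3] + 1L) %/% 2L
  lapply(keep, function(k) kb$input$grid[, , k])
}

#' Classifier inputs for a whole phantom cohort
#'
#' @param cohort result of [make_cohort].
#' @param params a [kbf_params].
#' @param dims 2 or 3.
#' @return list with `x` (inputs per patient), `y` (labels) and
#'   `patient_id`, directly consumable by [train_fold] and [run_cv].
#' @export
cohort_inputs <- function(cohort, params = kbf_params(), dims = 3) {
  x <- lapply(cohort$phantoms, function(p)
    classifier_input(p$flair, p$t1, p$brain_mask, params = params,
                     dims = dims))
  list(x = x, y = cohort$labels$label,
       patient_id = cohort$labels$patient_id)
}
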