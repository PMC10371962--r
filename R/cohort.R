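#' Two-center cohort specification (feature-table level)
#'
#' Describes a synthetic lesion cohort for testing the tabular stages
#' (harmonization, univariate statistics, modeling) without images: Gaussian
#' per-class features, a per-feature mean shift between outcome classes
#' (`effect_size`, in pooled within-class SD units) applied to a named
#' feature subset, and a per-center location/scale batch transform
#' x -> scale_c * x + offset_c (offset also in SD units).
#'
#' @param n_patients Integer length-2: patients in center 1 and center 2.
#' @param lesions_per_patient Integer vector sampled uniformly per patient.
#' @param prevalence Probability a lesion responds, in (0,1). Defaults to the
#'   75/126 responding fraction of a two-center lymphoma cohort.
#' @param n_features Number of features when `feature_names` is NULL.
#' @param feature_names Optional feature column names.
#' @param effect_size Mean shift (pooled-SD units) added to responding
#'   lesions for `effect_features`.
#' @param effect_features Names (or indices) of affected features; default
#'   the first 5.
#' @param batch_offset Length-2 additive offsets (SD units) per center.
#' @param batch_scale Length-2 positive multiplicative scales per center.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = c(20, 20), lesions_per_patient = 1:3,
                        prevalence = 75 / 126, n_features = 20,
                        feature_names = NULL, effect_size = 0,
                        effect_features = NULL,
                        batch_offset = c(0, 0), batch_scale = c(1, 1)) {
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0,1)", call. = FALSE)
  if (any(batch_scale <= 0)) stop("batch scales must be positive", call. = FALSE)
  if (any(n_patients < 5)) stop("need at least 5 patients per center", call. = FALSE)
  if (is.null(feature_names)) {
    feature_names <- sprintf("f%02d", seq_len(n_features))
  }
  if (is.null(effect_features)) {
    effect_features <- feature_names[seq_len(min(5, length(feature_names)))]
  } else if (is.numeric(effect_features)) {
    effect_features <- feature_names[effect_features]
  }
  stopifnot(all(effect_features %in% feature_names))
  structure(list(n_patients = as.integer(n_patients),
                 lesions_per_patient = as.integer(lesions_per_patient),
                 prevalence = prevalence, feature_names = feature_names,
                 effect_size = effect_size, effect_features = effect_features,
                 batch_offset = rep(batch_offset, length.out = 2),
                 batch_scale = rep(batch_scale, length.out = 2)),
            class = "cohort_spec")
}

assign_outcomes <- function(n, prevalence) {
  n_resp <- round(n * prevalence)
  n_resp <- min(max(n_resp, 1L), n - 1L) # both classes present
  sample(c(rep("responding", n_resp), rep("non-responding", n - n_resp)))
}

#' Simulate a two-center lesion feature table
#'
#' Features are standard Gaussian within class; responding lesions receive a
#' `effect_size` x SD mean shift on the effect features (the within-class SD
#' is 1 by construction, so the planted shift is exact); each center then
#' applies its location/scale batch transform. Outcome labels are allocated
#' to match the stated prevalence exactly (up to rounding). Fully
#' reproducible from the seed.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return A tibble with columns `lesion_id`, `patient_id`, `center_id`,
#'   `outcome`, then the feature columns.
#' @export
simulate_cohort <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  rows <- list()
  for (ctr in 1:2) {
    for (p in seq_len(spec$n_patients[ctr])) {
      nl <- if (length(spec$lesions_per_patient) == 1L) spec$lesions_per_patient
            else sample(spec$lesions_per_patient, 1)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        patient_id = sprintf("C%d_P%02d", ctr, p),
        center_id = sprintf("center%d", ctr),
        n_lesions = nl)
    }
  }
  pats <- dplyr::bind_rows(rows)
  tab <- tidyr::uncount(pats, .data$n_lesions)
  tab <- dplyr::select(tab, -dplyr::any_of("n_lesions"))
  tab <- dplyr::mutate(tab, lesion_id = sprintf("L%03d", dplyr::row_number()),
                       .before = 1)
  n <- nrow(tab)
  tab$outcome <- assign_outcomes(n, spec$prevalence)
  feat <- matrix(stats::rnorm(n * length(spec$feature_names)), nrow = n,
                 dimnames = list(NULL, spec$feature_names))
  resp <- tab$outcome == "responding"
  for (fn in spec$effect_features) feat[resp, fn] <- feat[resp, fn] + spec$effect_size
  for (ctr in 1:2) {
    in_ctr <- tab$center_id == sprintf("center%d", ctr)
    feat[in_ctr, ] <- feat[in_ctr, ] * spec$batch_scale[ctr] + spec$batch_offset[ctr]
  }
  dplyr::bind_cols(tab, tibble::as_tibble(feat))
}

id_columns <- function() c("lesion_id", "patient_id", "center_id", "outcome")

#' Feature columns of a feature table
#'
#' @param table A feature table (tibble).
#' @param prefix Optional prefix filter (e.g. `"dtp_"`).
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(table, prefix = NULL) {
  cols <- setdiff(names(table), id_columns())
  if (!is.null(prefix)) cols <- cols[startsWith(cols, prefix)]
  cols
}

#' Read / write a lesion feature table (CSV)
#'
#' Comma-separated, UTF-8, `.` decimal; the four mandatory identifier columns
#' (`lesion_id`, `patient_id`, `center_id`, `outcome`) come first, feature
#' columns follow in their stored order, which round-trips unchanged.
#'
#' @param path CSV path.
#' @return `read_feature_table()` returns a tibble; `write_feature_table()`
#'   its `path`, invisibly.
#' @export
read_feature_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(id_columns(), names(tab))
  if (length(miss)) {
    stop(sprintf("missing mandatory column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(tab$lesion_id)) stop("duplicate lesion_id", call. = FALSE)
  dplyr::relocate(tab, dplyr::all_of(id_columns()))
}

#' @rdname read_feature_table
#' @param table Feature table to write.
#' @export
write_feature_table <- function(table, path) {
  miss <- setdiff(id_columns(), names(table))
  if (length(miss)) {
    stop(sprintf("missing mandatory column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(table$lesion_id)) stop("duplicate lesion_id", call. = FALSE)
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' Simulate a two-center cohort through the full image chain
#'
#' Every lesion is generated as its own dual-time-point phantom study and
#' pushed through the complete image pipeline: Patlak-consistent simulation,
#' blood-pool reading, input-function scaling, Ki map computation, 30%
#' SUVmax segmentation, VOI transfer, and 65 + 65 feature extraction
#' (`static_` / `dtp_` column prefixes). A controlled outcome effect
#' (`effect_size`, pooled-SD units on `effect_features`) and per-center batch
#' transforms are then planted in feature space, so the planted effect size
#' is exact while all image stages are exercised.
#'
#' @param n_patients Length-2 patients per center.
#' @param lesions_per_patient Integer vector sampled per patient.
#' @param prevalence Responding fraction, in (0,1).
#' @param effect_size Planted mean shift (pooled-SD units).
#' @param effect_features Feature columns to shift; default a small set of
#'   `dtp_` texture and intensity features.
#' @param batch_offset,batch_scale Length-2 per-center location/scale batch
#'   transform (offset in pooled-SD units).
#' @param cfg A [pipeline_config()].
#' @param f Population [input_function()].
#' @param noise_cov Image noise CoV at (t1, t2).
#' @param seed Integer seed.
#' @return A feature table tibble with `static_`/`dtp_` feature columns.
#' @export
simulate_image_cohort <- function(n_patients = c(8, 8), lesions_per_patient = 1:3,
                                  prevalence = 75 / 126, effect_size = 0,
                                  effect_features = NULL,
                                  batch_offset = c(0, 0), batch_scale = c(1, 1),
                                  cfg = pipeline_config(), f = input_function(),
                                  noise_cov = c(0.05, 0.05), seed = 1) {
  set.seed(seed)
  rows <- list()
  lesion_no <- 0L
  for (ctr in 1:2) {
    for (p in seq_len(n_patients[ctr])) {
      nl <- if (length(lesions_per_patient) == 1L) lesions_per_patient
            else sample(lesions_per_patient, 1)
      for (l in seq_len(nl)) {
        lesion_no <- lesion_no + 1L
        lesion_seed <- sample.int(.Machine$integer.max, 1)
        feats <- simulate_single_lesion(cfg, f, noise_cov, lesion_seed)
        rows[[lesion_no]] <- dplyr::bind_cols(
          tibble::tibble(lesion_id = sprintf("L%03d", lesion_no),
                         patient_id = sprintf("C%d_P%02d", ctr, p),
                         center_id = sprintf("center%d", ctr)),
          feats)
      }
    }
  }
  tab <- dplyr::bind_rows(rows)
  tab$outcome <- assign_outcomes(nrow(tab), prevalence)
  tab <- dplyr::relocate(tab, dplyr::all_of(id_columns()))
  fcols <- feature_columns(tab)
  if (is.null(effect_features)) {
    effect_features <- paste0("dtp_", c("GLCM_Entropy", "GLCM_Energy",
                                        "HISTO_Uniformity", "Conventional_mean",
                                        "GLRLM_RLNU"))
  }
  stopifnot(all(effect_features %in% fcols))
  tab <- plant_class_effect(tab, effect_size, effect_features)
  for (ctr in 1:2) {
    in_ctr <- tab$center_id == sprintf("center%d", ctr)
    if (batch_scale[ctr] != 1 || batch_offset[ctr] != 0) {
      for (fn in fcols) {
        s <- stats::sd(tab[[fn]])
        if (!is.finite(s) || s == 0) s <- 1
        tab[[fn]][in_ctr] <- tab[[fn]][in_ctr] * batch_scale[ctr] +
          batch_offset[ctr] * s
      }
    }
  }
  tab
}

# One lesion's phantom study through the full image chain -> 65+65 features
simulate_single_lesion <- function(cfg, f, noise_cov, seed) {
  set.seed(seed)
  radius <- stats::runif(1, 8, 14)
  spec <- phantom_spec(
    dims = c(24L, 24L, 24L), spacing = c(4, 4, 4),
    background_suv = 0.4, background_ki = 0.001,
    lesions = list(list(centre = c(36, 36, 36), radius_mm = radius,
                        ki = stats::rlnorm(1, log(0.015), 0.3),
                        v = stats::runif(1, 0.2, 0.4),
                        texture_cor_mm = stats::runif(1, 6, 10),
                        texture_amp = stats::runif(1, 0.2, 0.5))),
    blood_pool = list(centre = c(76, 76, 76), radius_mm = 10, pure_plasma = TRUE),
    noise_cov = noise_cov)
  st <- simulate_dtp_study(spec, f, cfg$t1_min, cfg$t2_min)
  blood <- blood_pool_activity(st$suv_t1, st$blood_centre, st$blood_centre)
  f_pat <- scale_input_function(f, blood, cfg$t1_min)
  ki <- compute_ki_map(st$suv_t1, st$act_t2, f_pat, cfg$t1_min, cfg$t2_min,
                       scale_factor = cfg$ki_scale)
  bb <- which(st$lesion_masks[[1]]$mask, arr.ind = TRUE)
  pad <- 2L
  region <- list(lo = pmax(apply(bb, 2, min) - pad, 1L),
                 hi = pmin(apply(bb, 2, max) + pad, dim(st$suv_t1$data)))
  voi_suv <- threshold_segment(st$suv_t1, region, cfg$threshold_fraction)
  voi_ki <- transfer_voi(voi_suv, ki)
  feats <- extract_all(st$suv_t1, ki, voi_suv, voi_ki, cfg)
  wide <- c(stats::setNames(feats$static, paste0("static_", feats$feature)),
            stats::setNames(feats$dtp, paste0("dtp_", feats$feature)))
  tibble::as_tibble(as.list(wide))
}

#' Plant a controlled outcome effect into a feature table
#'
#' Adds `effect_size` pooled within-class standard deviations to the stated
#' feature columns for responding lesions, leaving everything else untouched.
#' This is how the cohort generators control the separability of the two
#' outcome classes exactly, independent of how the features were produced.
#'
#' @param table Feature table with an `outcome` column.
#' @param effect_size Mean shift in pooled-SD units (0 is a no-op).
#' @param features Feature columns to shift.
#' @return The modified table.
#' @export
plant_class_effect <- function(table, effect_size, features) {
  if (effect_size == 0) return(table)
  stopifnot(all(features %in% names(table)))
  resp <- table$outcome == "responding"
  for (fn in features) {
    x <- table[[fn]]
    s <- stats::sd(c(x[resp] - mean(x[resp]), x[!resp] - mean(x[!resp])))
    if (is.finite(s) && s > 0) table[[fn]][resp] <- x[resp] + effect_size * s
  }
  table
}
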