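outcome_binary <- function(labels, positive = "responding") {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) return(as.integer(labels != 0))
  as.integer(as.character(labels) == positive)
}

#' Spearman correlation of paired static and DTP features
#'
#' Rank correlation (average-rank tie handling) between each static feature
#' and its DTP counterpart over matched lesions, with the standard tier
#' assignment on |rho|: low < 0.5, moderate in \[0.5, 0.7), high >= 0.7.
#' Features with |rho| below 0.7 are the candidates carrying information not
#' present in the static image. Constant features have undefined rho and are
#' flagged.
#'
#' @param static,dtp Feature tables with identical lesion order and feature
#'   columns.
#' @param features Feature columns to compare; default all shared non-id
#'   columns.
#' @return A tibble with columns `feature`, `rho`, `p_value`, `tier`.
#' @export
spearman_pairs <- function(static, dtp, features = NULL) {
  if (is.null(features)) {
    features <- intersect(feature_columns(static), feature_columns(dtp))
  }
  if (!identical(static$lesion_id, dtp$lesion_id)) {
    stop("static and DTP tables must hold the same lesions in the same order",
         call. = FALSE)
  }
  if (nrow(static) < 3) stop("need at least 3 lesions", call. = FALSE)
  purrr::map_dfr(features, function(fn) {
    x <- static[[fn]]; y <- dtp[[fn]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(tibble::tibble(feature = fn, rho = NA_real_, p_value = NA_real_,
                            tier = "undefined"))
    }
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    rho <- unname(ct$estimate)
    tier <- if (abs(rho) < 0.5) "low" else if (abs(rho) < 0.7) "moderate" else "high"
    tibble::tibble(feature = fn, rho = rho, p_value = ct$p.value, tier = tier)
  })
}

#' ROC AUC with DeLong variance
#'
#' AUC as the Mann-Whitney pair statistic (ties counted 1/2) with its DeLong
#' placement-value variance and a two-sided normal p-value against AUC = 0.5.
#' `oriented = TRUE` reports max(AUC, 1 - AUC), the convention of a
#' direction-free per-feature screen; the raw AUC is kept alongside.
#'
#' @param scores Numeric scores, higher = more "positive" (raw orientation).
#' @param labels Binary outcome (character `responding`/`non-responding`,
#'   logical, or 0/1).
#' @param oriented Report the direction-free AUC?
#' @param positive Positive class label for character input.
#' @return A one-row tibble: `auc`, `auc_raw`, `var_delong`, `p_value`.
#' @export
roc_auc <- function(scores, labels, oriented = FALSE, positive = "responding") {
  y <- outcome_binary(labels, positive)
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  r <- pROC::roc(y, scores, quiet = TRUE, direction = "<")
  a <- as.numeric(pROC::auc(r))
  v <- suppressWarnings(pROC::var(r, method = "delong"))
  if (!is.finite(v)) v <- 0
  p <- if (v > 0) 2 * stats::pnorm(-abs((a - 0.5) / sqrt(v)))
       else as.numeric(a == 0.5)
  tibble::tibble(auc = if (oriented) max(a, 1 - a) else a,
                 auc_raw = a, var_delong = v, p_value = p)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors computed on the same lesions and
#' labels, using the covariance of DeLong placement values and a two-sided
#' normal p-value on z = dAUC / SE. Identical scores give dAUC = 0 and p = 1.
#'
#' @param scores_a,scores_b Score vectors on the same lesions.
#' @param labels Shared binary outcome.
#' @param positive Positive class label.
#' @return A one-row tibble: `auc_a`, `auc_b`, `delta_auc`, `z`, `p_value`.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels,
                               positive = "responding") {
  if (length(scores_a) != length(scores_b)) stop("mismatched rows", call. = FALSE)
  y <- outcome_binary(labels, positive)
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  ra <- pROC::roc(y, scores_a, quiet = TRUE, direction = "<")
  rb <- pROC::roc(y, scores_b, quiet = TRUE, direction = "<")
  aa <- as.numeric(pROC::auc(ra)); ab <- as.numeric(pROC::auc(rb))
  if (isTRUE(all.equal(scores_a, scores_b))) {
    return(tibble::tibble(auc_a = aa, auc_b = ab, delta_auc = 0, z = 0, p_value = 1))
  }
  tt <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  z <- unname(tt$statistic)
  if (!is.finite(z)) {
    if (abs(aa - ab) < .Machine$double.eps^0.5) {
      return(tibble::tibble(auc_a = aa, auc_b = ab, delta_auc = aa - ab,
                            z = 0, p_value = 1))
    }
    stop("zero DeLong SE with nonzero AUC difference (exact ties); test undefined",
         call. = FALSE)
  }
  tibble::tibble(auc_a = aa, auc_b = ab, delta_auc = aa - ab, z = z,
                 p_value = unname(tt$p.value))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment, q_(i) = min over j >= i of
#' p_(j) m / j, mapped back to the input order.
#'
#' @param pvals Numeric p-values in \[0, 1\].
#' @return Numeric q-values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Univariate per-feature screen across the four analysis arms
#'
#' For every feature, in each of the four arms (static / DTP, before / after
#' ComBat harmonization applied to all lesions), computes the direction-free
#' AUC against outcome with DeLong p-value and BH q-value (adjusted within
#' arm). Then runs the four paired DeLong cross-comparisons (harmonized vs
#' non-harmonized within image type; static vs DTP within harmonization
#' state) per feature, with BH adjustment per comparison, and tallies how
#' many features significantly improved, decreased, or did not differ at
#' q < `q_threshold`. The three counts partition the feature panel.
#'
#' @param table Feature table with `static_`/`dtp_` feature columns,
#'   `outcome` and `center_id`.
#' @param q_threshold Significance threshold on q-values.
#' @param positive Positive class label.
#' @return A list with tibbles `per_feature` (arm-wise AUC/p/q),
#'   `comparisons` (per-feature paired DeLong results) and `counts`
#'   (Table-style improved/decreased/no-difference tally).
#' @export
univariate_screen <- function(table, q_threshold = 0.05,
                              positive = "responding") {
  feats <- sub("^static_", "", feature_columns(table, "static_"))
  stopifnot(length(feats) > 0,
            setequal(paste0("dtp_", feats), feature_columns(table, "dtp_")))
  harmonized <- combat_apply(combat_fit(table), table)
  arms <- list(static_raw = list(tab = table, prefix = "static_"),
               dtp_raw = list(tab = table, prefix = "dtp_"),
               static_harmonized = list(tab = harmonized, prefix = "static_"),
               dtp_harmonized = list(tab = harmonized, prefix = "dtp_"))
  per_feature <- purrr::imap_dfr(arms, function(arm, arm_name) {
    res <- purrr::map_dfr(feats, function(fn) {
      dplyr::mutate(roc_auc(arm$tab[[paste0(arm$prefix, fn)]], arm$tab$outcome,
                            oriented = TRUE, positive = positive),
                    feature = fn, .before = 1)
    })
    res$q_value <- bh_fdr(res$p_value)
    dplyr::mutate(res, arm = arm_name, .before = 1)
  })
  comp_defs <- list(
    dtp_harmonized_vs_raw = c("dtp_raw", "dtp_harmonized"),
    static_harmonized_vs_raw = c("static_raw", "static_harmonized"),
    harmonized_static_vs_dtp = c("static_harmonized", "dtp_harmonized"),
    raw_static_vs_dtp = c("static_raw", "dtp_raw"))
  comparisons <- purrr::imap_dfr(comp_defs, function(def, comp_name) {
    a <- arms[[def[1]]]; b <- arms[[def[2]]]
    res <- purrr::map_dfr(feats, function(fn) {
      dplyr::mutate(
        delong_paired_test(a$tab[[paste0(a$prefix, fn)]],
                           b$tab[[paste0(b$prefix, fn)]],
                           table$outcome, positive = positive),
        feature = fn, .before = 1)
    })
    res$q_value <- bh_fdr(res$p_value)
    dplyr::mutate(res, comparison = comp_name, .before = 1)
  })
  counts <- comparisons |>
    dplyr::group_by(.data$comparison) |>
    dplyr::summarise(
      significantly_decreased = sum(.data$q_value < q_threshold & .data$auc_b < .data$auc_a),
      significantly_improved = sum(.data$q_value < q_threshold & .data$auc_b > .data$auc_a),
      .groups = "drop") |>
    dplyr::mutate(no_difference = length(feats) - .data$significantly_decreased -
                    .data$significantly_improved)
  list(per_feature = per_feature, comparisons = comparisons, counts = counts)
}
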