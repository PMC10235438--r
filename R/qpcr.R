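#' Nuclear proportion of a transcript from paired Ct values
#'
#' With cDNA synthesized from proportionally equal volumes of nuclear and
#' cytoplasmic RNA and perfect-doubling amplification, relative abundance
#' is proportional to `2^-Ct`, so the nuclear proportion is
#' `2^-ct_nuc / (2^-ct_nuc + 2^-ct_cyt)`.
#'
#' @param ct_nuc,ct_cyt Ct values (cycles) for the nuclear and cytoplasmic
#'   fractions; vectorized.
#' @return Proportion nuclear, in `[0, 1]`.
#' @export
compartment_proportion <- function(ct_nuc, ct_cyt) {
  if (any(!is.finite(ct_nuc)) || any(!is.finite(ct_cyt))) {
    stop("Ct values must be finite", call. = FALSE)
  }
  1 / (1 + 2^(ct_nuc - ct_cyt))
}

#' Arcsine square-root transform of proportions
#'
#' Variance-stabilizing transform used for statistics and SD calculation on
#' proportion data; results are back-transformed for presentation with
#' [arcsine_back()].
#'
#' @param p Proportions in `[0, 1]`; vectorized.
#' @return `asin(sqrt(p))`, radians.
#' @export
arcsine_transform <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  asin(sqrt(p))
}

#' @rdname arcsine_transform
#' @param x Transformed values in `[0, pi/2]`.
#' @export
arcsine_back <- function(x) sin(x)^2

#' Per-gene nuclear/cytoplasmic proportions from a Ct table
#'
#' Computes the nuclear proportion per (gene, replicate) pair, then
#' summarizes on the arcsine scale (mean and SD) and back-transforms the
#' mean for presentation.
#'
#' @param ct Tidy Ct table with columns `gene`, `replicate`, `fraction`
#'   (`"nuclear"`/`"cytoplasmic"`) and `ct`.
#' @return A tibble per gene: `n`, `prop_nuclear` (back-transformed mean),
#'   `asin_mean`, `asin_sd`, and the per-replicate proportions nested in
#'   `replicates`.
#' @export
compartment_table <- function(ct) {
  need <- c("gene", "replicate", "fraction", "ct")
  if (!all(need %in% names(ct))) {
    stop("Ct table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  wide <- tidyr::pivot_wider(ct, id_cols = c("gene", "replicate"),
    names_from = "fraction", values_from = "ct")
  if (anyNA(wide$nuclear) || anyNA(wide$cytoplasmic)) {
    stop("both fractions required for every (gene, replicate)", call. = FALSE)
  }
  wide$prop <- compartment_proportion(wide$nuclear, wide$cytoplasmic)
  wide$asin_prop <- arcsine_transform(wide$prop)
  out <- dplyr::summarise(dplyr::group_by(wide, .data$gene),
    n = dplyr::n(),
    asin_mean = mean(.data$asin_prop),
    asin_sd = sd(.data$asin_prop),
    replicates = list(tibble(replicate = replicate, prop = prop)),
    .groups = "drop")
  out$prop_nuclear <- arcsine_back(out$asin_mean)
  out[, c("gene", "n", "prop_nuclear", "asin_mean", "asin_sd", "replicates")]
}

#' Relative expression by the 2^-ddCt method
#'
#' Expression of a target gene normalized to a reference gene and relative
#' to a control condition, under perfect-doubling amplification.
#'
#' @param ct_target,ct_ref Target and reference-gene Ct in the condition of
#'   interest.
#' @param ct_target_ctrl,ct_ref_ctrl The same in the control condition.
#' @return Fold change (dimensionless); vectorized.
#' @export
relative_expression <- function(ct_target, ct_ref, ct_target_ctrl, ct_ref_ctrl) {
  ddct <- (ct_target - ct_ref) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
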