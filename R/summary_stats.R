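#' Mean OPD over the cell area
#'
#' The per-cell morphology summary: arithmetic mean of the OPD map over the
#' analysis mask, in nm.
#'
#' @param opd an [opd_map()] or numeric matrix (nm).
#' @param mask a [cell_mask()] with matching dimensions.
#' @return scalar (nm).
#' @export
mean_opd <- function(opd, mask) {
  if (inherits(opd, "opd_map")) opd <- unclass(opd)
  stopifnot(is.matrix(opd), inherits(mask, "cell_mask"))
  if (!identical(dim(opd), dim(mask$pixels))) abort("mask and map dimensions differ")
  mean(opd[mask$pixels])
}

#' Mean absolute value of a fluctuation map
#'
#' The per-cell dynamics summary: mean of the absolute values over all
#' (omega, q) bins of the raw-power fluctuation map. Power is non-negative,
#' so this equals the mean power; the absolute value guards renderings that
#' may be signed.
#'
#' @param fmap a [fluctuation_map()] or numeric matrix.
#' @return scalar (power units).
#' @export
mean_abs_fluct <- function(fmap) {
  p <- if (inherits(fmap, "fluctuation_map")) fmap$power else fmap
  stopifnot(is.matrix(p) || is.numeric(p))
  if (length(p) == 0) abort("empty fluctuation map")
  mean(abs(p), na.rm = TRUE)
}

#' Compare a per-cell summary statistic between two groups
#'
#' Two-sided two-sample test of the group difference; Welch's t-test by
#' default (robust to unequal variances), Mann-Whitney selectable. Degenerate
#' input (both groups constant and equal) returns p = 1.
#'
#' @param a,b numeric vectors (one value per cell), each with n >= 3.
#' @param method `"welch"` or `"wilcoxon"`.
#' @return p-value in `[0, 1]`.
#' @export
compare_groups <- function(a, b, method = c("welch", "wilcoxon")) {
  method <- match.arg(method)
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) < 3 || length(b) < 3) abort("each group needs at least 3 values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  if (method == "welch") {
    stats::t.test(a, b, var.equal = FALSE)$p.value
  } else {
    suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
  }
}

#' Per-cell summary statistics for a dataset
#'
#' Computes, for every cell of a dataset, the mean OPD over the analysis area
#' and the mean absolute fluctuation-map value — the two per-cell summaries
#' whose group histograms motivate the classifier.
#'
#' @param data a dataset tibble as returned by [simulate_classification_data()]
#'   (columns `cell_id`, `label`, and list-columns `video` or precomputed
#'   `mean_opd_nm` / `mean_abs_fluct` inputs).
#' @return a tibble with columns `cell_id`, `label`, `mean_opd_nm`,
#'   `mean_abs_fluct`.
#' @export
cell_summaries <- function(data) {
  stopifnot(is.data.frame(data))
  if (all(c("mean_opd_nm", "mean_abs_fluct") %in% names(data))) {
    return(dplyr::select(data, "cell_id", "label", "mean_opd_nm", "mean_abs_fluct"))
  }
  if (!"video" %in% names(data)) {
    abort("`data` must carry a `video` list-column or precomputed summaries")
  }
  purrr::pmap_dfr(data, function(cell_id, label, video, ...) {
    mask <- build_mask(video$frames[, , 1])
    fmap <- fluctuation_map(video, mask)
    tibble::tibble(cell_id = cell_id, label = label,
                   mean_opd_nm = mean_opd(mean_frame(video), mask),
                   mean_abs_fluct = mean_abs_fluct(fmap))
  })
}

#' Group comparison of the per-cell summaries
#'
#' @param summaries output of [cell_summaries()].
#' @param method passed to [compare_groups()].
#' @return a tibble with one row per summary statistic: group means and the
#'   between-group p-value.
#' @export
summarize_groups <- function(summaries, method = "welch") {
  stopifnot(all(c("label", "mean_opd_nm", "mean_abs_fluct") %in% names(summaries)))
  labs <- unique(summaries$label)
  if (length(labs) != 2) abort("exactly two groups are required")
  purrr::map_dfr(c("mean_opd_nm", "mean_abs_fluct"), function(stat) {
    a <- summaries[[stat]][summaries$label == labs[1]]
    b <- summaries[[stat]][summaries$label == labs[2]]
    tibble::tibble(statistic = stat,
                   mean_group1 = mean(a), mean_group2 = mean(b),
                   group1 = labs[1], group2 = labs[2],
                   p_value = compare_groups(a, b, method = method))
  })
}
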