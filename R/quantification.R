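#' Efficiency-weighted quantification cycles
#'
#' The common base method places every assay on a shared base-10 log scale
#' by weighting each quantification cycle by the log of its amplification
#' efficiency:
#' \deqn{C_q^{(w)} = \log_{10}(E) \cdot C_q}
#' With a perfect assay (E = 2, exact doubling each cycle) this compresses
#' cycles by \eqn{\log_{10} 2 \approx 0.301}; with E = 10 the weighted value
#' equals the raw cycle count. Weighted values from assays with different
#' efficiencies are directly comparable and may be averaged arithmetically,
#' because they already live on a log scale.
#'
#' @param wells A data frame of well records with columns `sample_id`,
#'   `gene`, `role` (`"target"` or `"reference"`), `cq` (quantification
#'   cycle, > 0) and `efficiency` (per-cycle amplification factor; 2 means
#'   perfect doubling).
#' @param strict If `TRUE`, efficiencies above 2.2 are an error rather than
#'   a warning (used by the file reader, where a value like 85 almost
#'   certainly means a percentage that must be converted as
#'   `E = 1 + pct/100`).
#'
#' @return The input as a tibble with an added `cq_w` column,
#'   `log10(efficiency) * cq`.
#'
#' @details
#' Validation rules: `cq` must be positive. `efficiency` must exceed 1
#' (E = 1 means no amplification, E < 1 decay); values in (1, 1.2] are
#' also rejected, with a hint that percentage efficiencies (e.g. 0.85 or
#' 85) must be converted to amplification factors as `E = 1 + pct/100`.
#' Efficiencies above 2.2 (faster than doubling by a wide margin) trigger
#' a warning, or an error when `strict = TRUE`.
#'
#' @examples
#' wells <- tibble::tibble(
#'   sample_id = "s1", gene = c("goi", "ref"),
#'   role = c("target", "reference"), cq = c(24.1, 21.7),
#'   efficiency = c(1.94, 1.99)
#' )
#' weight_cq(wells)
#' @seealso [normalize_cq()] for the reference-gene normalization step.
#' @export
weight_cq <- function(wells, strict = FALSE) {
  wells <- validate_wells(wells, strict = strict)
  dplyr::mutate(wells, cq_w = log10(.data$efficiency) * .data$cq)
}

well_columns <- c("sample_id", "gene", "role", "cq", "efficiency")

validate_wells <- function(wells, strict = FALSE) {
  if (!is.data.frame(wells)) {
    abort("`wells` must be a data frame of well records.")
  }
  missing_cols <- setdiff(well_columns, names(wells))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Missing well-table column(s): ",
      paste(missing_cols, collapse = ", "), "."
    ))
  }
  wells <- as_tibble(wells)
  if (nrow(wells) == 0) abort("No well records found.")
  row_label <- function(i) {
    paste0("row ", i, " (sample ", wells$sample_id[i],
           ", gene ", wells$gene[i], ")")
  }
  if (!is.numeric(wells$cq) || anyNA(wells$cq)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(wells$cq))))
    abort(paste0("Non-numeric or missing cq at ", row_label(bad[1]), "."))
  }
  if (!is.numeric(wells$efficiency) || anyNA(wells$efficiency)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(wells$efficiency))))
    abort(paste0("Non-numeric or missing efficiency at ",
                 row_label(bad[1]), "."))
  }
  bad_role <- which(!wells$role %in% c("target", "reference"))
  if (length(bad_role) > 0) {
    abort(paste0("Role must be 'target' or 'reference' at ",
                 row_label(bad_role[1]), "."))
  }
  bad_cq <- which(wells$cq <= 0)
  if (length(bad_cq) > 0) {
    abort(paste0("cq must be > 0 at ", row_label(bad_cq[1]), "."))
  }
  low_e <- which(wells$efficiency <= 1.2)
  if (length(low_e) > 0) {
    i <- low_e[1]
    abort(paste0(
      "Efficiency must be an amplification factor > 1.2 (2 = perfect ",
      "doubling); got ", format(wells$efficiency[i]), " at ", row_label(i),
      ". If this is a percentage efficiency, convert it as E = 1 + pct/100."
    ))
  }
  high_e <- which(wells$efficiency > 2.2)
  if (length(high_e) > 0) {
    i <- high_e[1]
    msg <- paste0(
      "Efficiency ", format(wells$efficiency[i]), " at ", row_label(i),
      " exceeds 2.2 (faster than doubling). If this is a percentage, ",
      "convert it as E = 1 + pct/100."
    )
    if (strict) abort(msg) else warn(msg)
  }
  wells
}

#' Reference-normalized weighted delta-Cq values
#'
#' Normalizes each target gene's weighted quantification cycle against the
#' arithmetic mean of the weighted values of the reference gene(s) measured
#' in the same sample:
#' \deqn{\Delta C_q^{(w)} = C_{q,\mathrm{GOI}}^{(w)} -
#'   \frac{1}{n}\sum_{i=1}^{n} C_{q,\mathrm{REF}_i}^{(w)}}
#' The arithmetic mean is correct here (rather than the geometric mean
#' used on linear-scale quantities) because weighted values are already on
#' the base-10 log scale. Higher \eqn{\Delta C_q^{(w)}} means *lower*
#' expression of the target.
#'
#' @param weighted A data frame as returned by [weight_cq()]: well records
#'   plus a `cq_w` column. Technical replicates must already be collapsed
#'   to one row per (sample, gene).
#'
#' @return A tibble with one row per (sample, target gene): columns
#'   `sample_id`, `gene`, `delta_cq`, `n_refs`.
#' @examples
#' wells <- tibble::tibble(
#'   sample_id = "s1", gene = c("goi", "r1", "r2"),
#'   role = c("target", "reference", "reference"),
#'   cq = c(24.1, 21.7, 22.3), efficiency = c(1.94, 1.99, 1.91)
#' )
#' normalize_cq(weight_cq(wells))
#' @export
normalize_cq <- function(weighted) {
  if (!is.data.frame(weighted) || !"cq_w" %in% names(weighted)) {
    abort("`weighted` must come from weight_cq() (needs a cq_w column).")
  }
  refs <- dplyr::filter(weighted, .data$role == "reference")
  targets <- dplyr::filter(weighted, .data$role == "target")
  if (nrow(targets) == 0) abort("No target-gene wells found.")
  ref_means <- refs %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::summarise(
      ref_mean = mean(.data$cq_w), n_refs = dplyr::n(), .groups = "drop"
    )
  no_ref <- setdiff(unique(targets$sample_id), ref_means$sample_id)
  if (length(no_ref) > 0) {
    abort(paste0("No reference-gene wells for sample(s): ",
                 paste(no_ref, collapse = ", "), "."))
  }
  targets %>%
    dplyr::inner_join(ref_means, by = "sample_id") %>%
    dplyr::transmute(
      sample_id = .data$sample_id,
      gene = .data$gene,
      delta_cq = .data$cq_w - .data$ref_mean,
      n_refs = .data$n_refs
    )
}

#' Normalize one weighted value against explicit references
#'
#' Scalar form of the normalization in [normalize_cq()], for callers that
#' hold weighted values directly rather than a well table.
#'
#' @param goi Weighted Cq of the gene of interest (a single value).
#' @param refs Numeric vector of weighted Cq values for the reference
#'   gene(s); must be non-empty.
#' @return `goi - mean(refs)`.
#' @examples
#' delta_cq(6, c(4, 5)) # 1.5
#' @export
delta_cq <- function(goi, refs) {
  if (length(goi) != 1 || !is.finite(goi)) {
    abort("`goi` must be a single finite weighted Cq value.")
  }
  if (length(refs) == 0) {
    abort("At least one reference weighted Cq value is required.")
  }
  if (!all(is.finite(refs))) abort("Reference values must be finite.")
  goi - mean(refs)
}

#' Convert between delta-delta-Cq and relative expression ratio
#'
#' The relative expression ratio is \eqn{R = 10^{-\Delta\Delta C_q^{(w)}}}
#' and its inverse is \eqn{\Delta\Delta C_q^{(w)} = -\log_{10} R}. Base 10
#' is fixed throughout the package; mixing log bases silently corrupts
#' ratios, so no base argument is exposed.
#'
#' @param ddcq Finite numeric vector of weighted delta-delta-Cq values.
#' @return For `ddcq_to_ratio()`, the ratio `10^(-ddcq)` (> 0, strictly
#'   decreasing in `ddcq`); for `ratio_to_ddcq()`, `-log10(r)`.
#' @examples
#' ddcq_to_ratio(0)      # 1: no change
#' ddcq_to_ratio(1)      # 0.1: one log decade lower expression
#' ratio_to_ddcq(0.666)
#' @export
ddcq_to_ratio <- function(ddcq) {
  if (!is.numeric(ddcq) || !all(is.finite(ddcq))) {
    abort("`ddcq` must be finite numeric.")
  }
  10^(-ddcq)
}

#' @param r Positive numeric vector of relative expression ratios.
#' @rdname ddcq_to_ratio
#' @export
ratio_to_ddcq <- function(r) {
  if (!is.numeric(r) || !all(is.finite(r)) || any(r <= 0)) {
    abort("Expression ratios must be finite and > 0.")
  }
  -log10(r)
}
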