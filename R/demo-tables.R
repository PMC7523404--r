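# Embedded hypothetical example datasets, one per analysis case.
# Only the *input* columns are stored; every derived quantity (fitted
# slope, ratios, confidence bands, contrasts) is recomputed by the
# package, never read back from a stored answer.

demo_table_store <- local({
  conc <- c(8.7, 8.9, 9.4, 9.5, 9.8, 10.1, 10.2, 10.4, 10.6, 10.9)
  dcq1 <- c(0.633, 0.568, 0.534, 0.474, 0.487, 0.428, 0.387, 0.398,
            0.360, 0.296)
  list(
    # hormone concentration vs delta-Cq, tight fit
    t1 = tibble::tibble(hormone_conc = conc, delta_cq = dcq1),
    # same design, noisier response
    t2 = tibble::tibble(
      hormone_conc = conc,
      delta_cq = c(0.683, 0.568, 0.598, 0.424, 0.537, 0.428, 0.337,
                   0.491, 0.360, 0.334)
    ),
    # delta-Cq as predictor of a behavioural response (minutes)
    t4 = tibble::tibble(delta_cq = dcq1, huddling_min = conc),
    # delta-Cq of gene A predicting delta-Cq of gene B
    t5 = tibble::tibble(
      delta_cq_a = dcq1,
      delta_cq_b = c(0.882, 0.845, 0.833, 0.829, 0.811, 0.806, 0.798,
                     0.766, 0.771, 0.755)
    ),
    # cell density (raw scale; log-transformed internally) vs delta-Cq
    t6 = tibble::tibble(
      cells_per_nl = c(385.61, 260.29, 176.41, 115.56, 74.72, 49.29,
                       33.37, 23.12),
      delta_cq = c(0.345, 0.368, 0.381, 0.405, 0.433, 0.445, 0.468,
                   0.488)
    ),
    # delta-Cq vs larval length at pupation (log-y relationship)
    t7 = tibble::tibble(
      delta_cq = c(0.345, 0.368, 0.381, 0.405, 0.433, 0.445, 0.468,
                   0.488),
      larval_length_mm = c(8.23, 12.96, 16.49, 24.44, 44.89, 54.76,
                           75.45, 110.39)
    ),
    # three diets across a temperature gradient (ANCOVA)
    t8 = tibble::tibble(
      group = rep(c("control", "treatment1", "treatment2"), each = 8),
      x = rep(seq(22, 36, by = 2), times = 3),
      delta_cq = c(
        0.511, 0.540, 0.615, 0.694, 0.798, 0.801, 0.895, 0.985,
        0.238, 0.241, 0.394, 0.401, 0.452, 0.511, 0.631, 0.673,
        0.236, 0.261, 0.388, 0.424, 0.462, 0.513, 0.586, 0.695
      )
    )
  )
})

#' Built-in hypothetical example datasets
#'
#' Small worked datasets, one per analysis case, used throughout the
#' documentation and tests:
#'
#' * `1` - hormone concentration (pg/mL) vs weighted delta-Cq (tight
#'   linear relationship; mean concentration 9.85).
#' * `2` - same design with a noisier response.
#' * `3` - identical inputs to dataset 1 (it exists to illustrate a
#'   different baseline policy, x0 = max; the inputs are unchanged).
#' * `4` - weighted delta-Cq as predictor of huddling time (minutes).
#' * `5` - delta-Cq of gene A predicting delta-Cq of gene B.
#' * `6` - bacterial density (cells/nL, raw scale) vs delta-Cq; the
#'   relationship is linear in log10(density).
#' * `7` - delta-Cq vs larval length at pupation (mm); linear in
#'   log10(length).
#' * `8` - delta-Cq across a 22-36 degree C temperature gradient under a
#'   control and two treatment diets (24 rows; ANCOVA).
#'
#' Only input columns are returned; fitted slopes, ratios and intervals
#' must be recomputed with the package's own functions.
#'
#' @param id Integer 1-8.
#' @return A tibble.
#' @examples
#' demo_table(1)
#' fit_ols(demo_table(6), log_x = TRUE)
#' @export
demo_table <- function(id) {
  if (length(id) != 1 || !id %in% 1:8) {
    abort("`id` must be a single integer between 1 and 8.")
  }
  key <- paste0("t", if (id == 3) 1 else id)
  demo_table_store[[key]]
}
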