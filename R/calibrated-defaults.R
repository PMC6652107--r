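# Shipped rate coefficients (day^-1). Obtained by running
# fit_model(default_calibration_targets(), fit_mapping = TRUE,
# constraint_weight = 50) and keeping the constraint-satisfying
# optimum; see calibrated_parameters() and check_constraints().
.CALIBRATED <- c(
  k_homeostasis = 0.006889,
  k_EH = 1.885673,
  k_HK = 0.016022,
  k_HM = 0.035359,
  k_HE = 0.003318,
  k_ME = 0.049222
)

# Observable mapping estimated alongside the shipped coefficients:
# measurement = scale * model + offset. Volume is the frozen % scale;
# the macrophage/Kupffer scales are % of nucleated cells per unit
# compartment fraction, the angiogenesis scale is area-ratio units per
# day^-1 of endothelial growth.
.CALIBRATED_MAPPING <- list(
  total_macrophages = c(161.430641, -7.3959694),
  kupffer = c(1e-06, 5.9999999),
  angiogenesis = c(71.888536, 0.1491984)
)

#' Observable mapping shipped with the calibrated coefficients
#'
#' The affine model-to-measurement mapping estimated during the
#' default calibration (see [calibrated_parameters()]).
#'
#' @return An `observable_mapping`.
#' @export
calibrated_mapping <- function() {
  observable_mapping(
    total_macrophages = .CALIBRATED_MAPPING$total_macrophages,
    kupffer = .CALIBRATED_MAPPING$kupffer,
    angiogenesis = .CALIBRATED_MAPPING$angiogenesis
  )
}
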