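# hand-built cohort rows for I/O and prediction tests; every field valid
# unless overridden

manual_eye <- function(eye_id = "E1", patient_id = eye_id, laterality = "OD",
                       age = 70, sex = "F", axial_length = 24, iol_power = 18,
                       pre24 = c(43, 44, 90), pre33 = pre24,
                       post24 = pre24, post33 = pre33,
                       ref = c(0, 0, 0),
                       bcva_decimal = 1.0, corneal_irregularity = 0.2) {
  tibble::tibble(
    patient_id = patient_id, eye_id = eye_id, laterality = laterality,
    age = age, sex = sex, axial_length = axial_length, iol_power = iol_power,
    preop_flat_k_24 = pre24[1], preop_steep_k_24 = pre24[2],
    preop_steep_axis_24 = pre24[3],
    preop_flat_k_33 = pre33[1], preop_steep_k_33 = pre33[2],
    preop_steep_axis_33 = pre33[3],
    postop_flat_k_24 = post24[1], postop_steep_k_24 = post24[2],
    postop_steep_axis_24 = post24[3],
    postop_flat_k_33 = post33[1], postop_steep_k_33 = post33[2],
    postop_steep_axis_33 = post33[3],
    ref_sphere = ref[1], ref_cylinder = ref[2], ref_axis = ref[3],
    corneal_irregularity = corneal_irregularity, bcva_decimal = bcva_decimal)
}

manual_cohort <- function(...) dplyr::bind_rows(...)

# spectacle-plane refraction whose corneal-plane refractive astigmatism is
# exactly (magnitude @ steep_axis); lets tests close the loop by hand
ref_for_corneal_astig <- function(magnitude, steep_axis, se = 0,
                                  vertex_distance = 0.012) {
  corneal <- c(se + magnitude / 2, -magnitude,
               astigzone::normalize_axis(steep_axis + 90))
  p1 <- corneal[1]
  p2 <- corneal[1] + corneal[2]
  q1 <- p1 / (1 + vertex_distance * p1)
  q2 <- p2 / (1 + vertex_distance * p2)
  c(q1, q2 - q1, corneal[3])
}

noiseless_generator <- function(n_eyes = 40, seed = 11,
                                pca_true = astigzone::pca_fixed_atr(0.30), ...) {
  astigzone::generator_config(
    n_eyes = n_eyes, seed = seed, pca_true = pca_true,
    sia_magnitude = 0, sia_sd = 0,
    k_noise_sd = 0, mean_k_noise_sd = 0, refraction_noise_sd = 0, ...)
}
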