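# Shared fixtures, all built in code.

# identity calibration curve: mu(theta) = theta, constant curve error
identity_curve <- function(theta_min = 2500, theta_max = 6000,
                           sigma_curve = 0, knot_step = 1) {
  new_calcurve(seq(theta_min, theta_max, by = knot_step),
               seq(theta_min, theta_max, by = knot_step),
               rep(sigma_curve, length(seq(theta_min, theta_max, by = knot_step))))
}

# wiggly 20-knot synthetic curve spanning the study era
wiggly_curve_20 <- function() {
  theta <- seq(3400, 5300, length.out = 20)
  mu <- theta + 40 * sin(theta / 150) + 15 * cos(theta / 47)
  sig <- 8 + 4 * abs(sin(theta / 200))
  new_calcurve(theta, mu, sig)
}

# canonical toy date table
toy_dates <- function(c14_age, error, site_id = "s1", region = "EJ",
                      material = "charcoal", site_type = "settlement") {
  n <- length(c14_age)
  data.frame(
    lab_id = sprintf("LAB-%03d", seq_len(n)),
    c14_age = c14_age,
    error = rep_len(error, n),
    site_id = rep_len(site_id, n),
    region = rep_len(region, n),
    material = rep_len(material, n),
    site_type = rep_len(site_type, n),
    stringsAsFactors = FALSE
  )
}

# study-era axis padded by 100 yr
study_axis <- function(step = 1) cal_axis(2950, 1600, step)
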