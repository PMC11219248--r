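# Shared fixtures: the reference-cohort mean femur and small helpers.

ref_distances <- c(me_fj = 29.4, le_fj = 21.2, me_ej = 25.1, le_ej = 21.3,
                   ml = 75.1)

ref_spec <- function(...) {
  femur_spec(side = "right", ml = 75.1, me_fj = 29.4, le_fj = 21.2,
             me_ej = 25.1, le_ej = 21.3, ...)
}

measured_distances <- function(meas) {
  unlist(meas[c("me_fj", "le_fj", "me_ej", "le_ej", "ml")])
}

measured_ratios <- function(meas) {
  unlist(meas[c("ratio_me_fj", "ratio_le_fj", "ratio_me_ej", "ratio_le_ej")])
}

random_unit <- function() unitize(stats::rnorm(3))
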