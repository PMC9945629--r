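# shared fixtures, built in code

rodent <- rodent_recirc_params()

quick_friberg <- function(gamma = 0.1) {
  friberg_params(C0 = 5000, mtt = 3, kcirc = 0.25, gamma = gamma)
}

neutrophil_truth <- list(C0 = 5000, mtt = 3.0, kcirc = 0.25, gamma = 0.08,
                         n_transit = 3, spike = 0.2, bm_surviving = 0.03,
                         ramp_start = 1, ramp_end = 14, ramp_shape = "linear")

# circulating values as a plain tibble
circ_of <- function(traj) leucokin::circulating_series(traj)

make_blood_counts <- function() {
  tibble::tibble(
    neutrophils = c(4000, 1000, 2000),
    lymphocytes = c(1000, 1000, 400),
    monocytes   = c(250, 1000, 400))
}
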