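# Shared fixtures, built in code and cached per test file.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) assign(name, build(), envir = .fixtures)
  .fixtures[[name]]
}

std_geom <- function() arm_geometry(0.30, 0.25)
std_layout <- function() build_target_layout(std_geom(), 0.30)

clean_trial <- function() {
  fixture("clean_trial", function()
    synth_trial("anterior_reaching_rest_height", std_layout(), std_geom(),
                impairment_params(seed = 11)))
}

emg_trial <- function() {
  fixture("emg_trial", function()
    synth_emg(synth_trial("anterior_reaching_rest_height", std_layout(),
                          std_geom(), impairment_params(seed = 12))))
}

vnorm_test <- function(v) sqrt(sum(v^2))
deg2rad_test <- function(x) x * pi / 180

# dense-grid root of the minimum-jerk speed fraction: first tau with
# 30 tau^2 (1-tau)^2 >= frac * 1.875 (independent onset oracle)
mj_onset_tau_oracle <- function(frac = 0.10) {
  tau <- seq(0, 0.5, by = 1e-6)
  tau[which(30 * tau^2 * (1 - tau)^2 >= frac * 1.875)[1]]
}
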