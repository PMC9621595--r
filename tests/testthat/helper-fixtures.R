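default_params <- function(...) model_parameters(...)
default_config <- function(...) chip_config(...)

# parameters with all reactions switched off (pure flow system)
inert_params <- function(...) {
  model_parameters(E_G0 = 0, CL_I_spheroids = 0, S_I0 = 0, Imax_Si = 0,
                   sigma_max = 0, k_v = 0, EGP = 0, ...)
}

# small two-condition dataset built directly in code
tiny_dataset <- function() {
  data.frame(
    series_id = rep(c("co:hyper:glu", "co:hyper:ins"), each = 4),
    observable = rep(c("glucose", "insulin"), each = 4),
    culture_type = "co-culture", regime = "hyper", gtt = "d1",
    time_h = rep(c(0, 8, 24, 48), 2),
    mean = c(11, 9.9, 7.4, 4.7, 0, 150, 300, 320),
    sem = c(0.6, 0.7, 0.5, 0.4, 0.5, 12, 25, 30),
    n = 5, stringsAsFactors = FALSE)
}
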