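# Shared fixtures: built-in registry with synthetic kq_ecal values filled in
# (the package ships kq_ecal unset; 0.9 here is a test placeholder, not a
# literature value), and the example kQ,Qo grid installed with the package.

demo_registry <- function(kq_ecal = 0.9) {
  vals <- rep(kq_ecal, 4)
  names(vals) <- c("PTW 30013", "IBA CC13", "Exradin A1Sl", "Exradin A11")
  set_kq_ecal(builtin_registry(), vals)
}

example_kq_table <- function() {
  load_kq_table(system.file("extdata", "kq_qo_example.csv", package = "ebcal"))
}

toy_kq_table <- function() {
  kq_table(data.frame(chamber = "toy",
                      r50_cm = c(4.0, 5.0),
                      kq_qo = c(0.911, 0.908)))
}

demo_cylindrical <- function(kq_ecal = NULL) {
  chamber_spec("demo-cyl", "none", "cylindrical",
               nd_w_gy_per_nc = 0.05, fit_model = "power",
               fit_a = 0.95, fit_b = 0.1, fit_c = 0.5,
               cavity_radius_cm = 0.6, kq_ecal = kq_ecal)
}

demo_parallel_plate <- function(kq_ecal = NULL, epom_shift_cm = 0.177) {
  chamber_spec("demo-pp", "none", "parallel_plate",
               nd_w_gy_per_nc = 0.05, fit_model = "exponential",
               fit_a = 0.99, fit_b = 0.11, fit_c = 2.9,
               epom_shift_cm = epom_shift_cm, kq_ecal = kq_ecal)
}
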