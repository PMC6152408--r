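# noise-free static titration with known (kb, n); corrected = TRUE
make_static_series <- function(kb, n, F0 = 1000,
                               concs = default_ligand_concs(),
                               temperature = 297) {
  simulate_titration(ground_truth(kb = kb, n = n, F0 = F0),
                     ligand_concs = concs, temperature = temperature)
}

# binding_fit stub for classifier tests that take fits as input
fake_binding_fit <- function(log_kb, temperature = 297) {
  structure(list(log_kb = log_kb, kb = 10^log_kb, n = 1, r_squared = 0.99,
                 temperature = temperature, n_points = 7),
            class = "binding_fit")
}

fake_sv_fit <- function(ksv, temperature, tau0 = 1e-8) {
  structure(list(ksv = ksv, intercept = 1, kq = ksv / tau0,
                 r_squared = 0.99, temperature = temperature),
            class = "stern_volmer_fit")
}
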