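## Small model builders shared across test files.

## single membrane species, pure diffusion
toy_diffusion_model <- function(D = 1, n0 = 50) {
  rd_model(list(species_spec("X", "membrane", D)), list(),
           init = c(X = n0))
}

## membrane/cytosol two-state shuttling at rates on/off
toy_shuttle_model <- function(on = 4, off = 6.5, n0 = 200,
                              D_c = 1, D_m = 0.01) {
  rd_model(list(species_spec("Mc", "cytosol", D_c, carries = "m"),
                species_spec("Mm", "membrane", D_m, carries = "m")),
           list(uni_reaction("Mc", "Mm", on, "cyto_to_mem", name = "on"),
                uni_reaction("Mm", "Mc", off, "mem_to_cyto", name = "off")),
           init = c(Mc = n0))
}

## reference benchmark microscopic parameters (diffusion control = 50)
fig2_micro <- function() micro_params(k_micro = 0.25, rho = 0.005,
                                      D_tot = 0.005)
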