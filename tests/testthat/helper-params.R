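# shared fixtures: the wild-type and mutant kinetic parameters used
# throughout the suite
wt_bond <- function() single_bond_params(0.5, 13.5, "WT_2mM_Ca")
mut_bond <- function() single_bond_params(1.4, 1.8, "R113G")
wt_dimer <- function() avidity_params(wt_bond(), k_on = 6.2e4,
                                      C_eff0 = 465e-6, f_c = 10)
mut_dimer <- function() avidity_params(mut_bond(), k_on = 6.2e4,
                                       C_eff0 = 465e-6, f_c = 10)
het_params <- function() hetero_avidity_params(wt_bond(), mut_bond(),
                                               6.2e4, 6.2e4, 465e-6, 10, 10)
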