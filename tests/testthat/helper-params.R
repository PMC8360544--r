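# Shared fixtures: the bundled published inputs, loaded once per test run.
base_params <- load_parameter_set()

# Full-precision control pneumonia probability used in several identities.
p_pn_control <- 39 / 931
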