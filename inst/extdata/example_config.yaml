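# Example configuration for the command-line `simulate` subcommand.
# Omitted keys keep the reference defaults (see ?sim_config).
architecture: ring1d
n_steps: 1000000
epsilon_learn: 0.005
seed: 1
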