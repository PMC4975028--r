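# Example run configuration for fgmcohorts.
# Exactly one of sigma2 / E_S may be given; E_S implies sigma2 = |E_S| / m.
n: 10
m: 3
E_S: -0.012
U: 0.003
N: 10000
w0: 0.5
generations: 1000
record_every: 1
seed: 42
placement: random_direction
replicates: 3
out_dir: fgm-out
noise_variance: 0.02
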