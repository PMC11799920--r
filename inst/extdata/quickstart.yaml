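# Quickstart: 4 heterogeneous synthetic clients, 32x32 phantoms, 10 rounds.
clients: 4
rounds: 10
local_epochs: 2
batch_size: 4
lr: 0.002
strategy: paf_fed
r_mode: adaptive
r0: 0.0
r1: 0.5
seed: 42
heterogeneity: 0.8
n_per_client: 40
image_size: 32
n_classes: 4
depth: 2
base_width: 8
augment: true
eval_every: 1
out_dir: freqfed_quickstart
log_level: info
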