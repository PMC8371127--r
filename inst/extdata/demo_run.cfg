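# Demo pipeline: simulate a small dataset, estimate site rates, run the
# slow-fast procedure, Dollo reconstruction and profile ordination.
out_dir = phylosf_demo
stages = simulate,rates,slowfast,dollo,profiles
seed = 5
sim.n_taxa = 8
sim.n_sites = 200
sim.alpha = 0.5
sim.n_traits = 40
step = 0.05
n_bootstrap = 10
alpha = 0.5
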