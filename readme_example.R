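suppressMessages(library(sosampler))
profs <- gen_toy_proteins(20, L = 20, n_binding = 2, shift = 4, seed = 7)
pd <- profiles_to_dataset(profs)
dim(pd$dataset$features)
spec <- classifier_spec("gaussian", c_grid = 8, gamma_grid = 0.01, seed = 7)
without <- cross_validate(pd$dataset, spec, groups = pd$groups,
                          sampler = "none", k = 5, policy = "max_mcc", seed = 7)
with_sos <- cross_validate(pd$dataset, spec, groups = pd$groups,
                           sampler = "sos", k = 5, policy = "max_mcc", seed = 7,
                           sos_cfg = sos_config(c_low = 0.5, c_high = 0.95))
print(without)
print(with_sos)
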