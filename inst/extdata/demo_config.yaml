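# Bundled demonstration configuration: every pipeline stage from one
# seed, at a scale that completes in well under five minutes on one CPU.
# Values omitted here fall back to the package defaults, which encode
# the study conditions (F2 of 960 progeny, 480 per dose arm, bulks of
# 89 resistant / 75 susceptible, 100x pooled depth, causal locus at
# 8.4 Mb on a 15-Mb chromosome plus a 10-Mb null chromosome).
seed: 1
out_dir: bsamap_demo
simulate:
  marker_spacing: 10000
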