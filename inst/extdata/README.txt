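printed_steroids_subset.csv

A small transcribed SUBSET of a published steroid concentration table
(ug/g dry weight) for a drained degraded bog site (AV-D) at 10/30/80 cm,
plus the ergosterol entry for a near-natural site (PU-N). Only columns that
could be transcribed unambiguously are included; "ND" marks printed
non-detects. Used in examples and tests of the stanol/sterol degradation
ratio and the fungal marker flag.

design_example.yaml

Example simulator design consumed by the command-line wrapper
(inst/cli/peatlipid.R simulate): a six-site, three-depth layout with two
degraded, two near-natural and two restored sites.
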