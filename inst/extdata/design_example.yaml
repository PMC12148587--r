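# Six-site, three-depth simulated survey: two degraded, two near-natural,
# two extracted-and-restored sites.
design:
  - {site: AV-D,  status: degraded_drained,   depths: [10, 30, 80]}
  - {site: AV-ED, status: degraded_extracted, depths: [10, 30, 80]}
  - {site: PU-N,  status: natural,            depths: [10, 30, 80]}
  - {site: PI-ER, status: restored,           depths: [10, 30, 80]}
  - {site: BK-N,  status: natural,            depths: [10, 30, 80]}
  - {site: BK-ER, status: restored,           depths: [10, 30, 80]}
total_mass: 500
noise_sigma: 0.2
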