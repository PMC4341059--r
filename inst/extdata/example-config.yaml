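# Example fluorosim configuration: synthetic proteome, realistic error load.
synthetic_n: 100
synthetic_composition: human
protease: gluc
anchor: cysteine
scheme: K+Y
cycles: 30
depth: 200
dye_failure: 0.15
edman_efficiency: 0.94
photobleach_half_life_minutes: 30
exposure_seconds: 1
seed: 17
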