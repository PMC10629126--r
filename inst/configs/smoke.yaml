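# Minimal end-to-end smoke run: tiny synthetic set, fast methods.
generator:
  n: 20
  soil_fraction: 0.3
  image_size: [64, 64]
  seed: 7
standardize_size: 48
threshold: 0.5
methods:
  - name: dummy
  - name: adaptive
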