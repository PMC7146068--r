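{
  "duration": 2500,
  "dt": 0.1,
  "tile_grid": [1, 1],
  "tile_size": 1000,
  "seed": 1,
  "warmup": 500,
  "boundary": "periodic",
  "n_workers": 1
}
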