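{
  "name": "instrument",
  "description": "Confocal polarization-imaging instrument profile.",
  "g_true": 0.75,
  "field_of_view_um": 205,
  "image_size_px": 512,
  "bit_depth": 8,
  "photon_noise": true,
  "read_noise_sd": 1,
  "background_level": 5,
  "frames_per_acquisition": 1
}
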