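# Synthetic example: experiment geometry (flat single panel)
wavelength_A: 1.0
detector_distance_mm: 100
pixel_size_mm: 0.1
beam_center_px: [500, 500]
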