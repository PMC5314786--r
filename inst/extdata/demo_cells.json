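[
  {"cell_id": "cell_001", "length_um": 2.6, "radius_um": 0.48, "center": [4.1, 3.2], "orientation": 0.12},
  {"cell_id": "cell_002", "length_um": 3.4, "radius_um": 0.51, "center": [8.9, 6.7], "orientation": -1.05},
  {"cell_id": "cell_003", "length_um": 4.1, "radius_um": 0.50, "center": [2.4, 9.8], "orientation": 0.78}
]
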