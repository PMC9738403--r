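# Compact synthetic-city run: a 2.8 x 2.8 km town with one rail and one bus
# line. Paper-free defaults (walking 1.2 m/s, bus 40 km/h, rail 70 km/h,
# 30 s dwell) apply to everything not set here.
seed: 7
city:
  grid_nx: 8
  grid_ny: 8
  block_spacing: 400
  n_districts: 3
  raster_cell: 200
  pop_centers:
    x: [900.0, 2000.0]
    "y": [900.0, 2300.0]
    total: [40000.0, 40000.0]
    decay: [700.0, 900.0]
  facility_specs:
    class: [clinic, pharmacy]
    "n": [8, 15]
    process: [thomas, thomas]
    parents: [2, 3]
    cluster_sd: [300.0, 250.0]
  transit_specs:
    line_id: [r1, b1]
    mode: [rail, bus]
    axis: [row, col]
    index: [4, 4]
    station_spacing: [1200.0, 400.0]
access:
  thresholds_min: [10.0, 20.0, 40.0]
  buffer_width: 200.0
kde:
  radius: 600.0
  cell_size: 200.0
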