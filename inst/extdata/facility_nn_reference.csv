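class,r1bar_m,rebar_m,R_reported,spatial_structure_type
tertiary_A,1741.02,7250.47,0.24,aggregation
general,739.10,1795.44,0.41,aggregation
specialist,330.15,1305.47,0.25,aggregation
community,1068.03,1772.59,0.60,aggregation
clinic,260.44,706.41,0.37,aggregation
pharmacy,79.34,380.39,0.21,aggregation
rail_stations,1164.27,2860.85,0.41,aggregation
bus_stops,291.69,606.15,0.48,aggregation
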