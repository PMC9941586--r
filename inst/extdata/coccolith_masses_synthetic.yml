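# Synthetic example coccolith mass table (placeholder values, not literature
# estimates): coccoliths per intact coccosphere and single-coccolith calcite
# mass in pg CaCO3. Replace per assemblage before use on real samples.
Emiliania huxleyi:
  coccoliths_per_sphere: 20
  coccolith_mass_pg: 2.5
Coccolithus pelagicus:
  coccoliths_per_sphere: 12
  coccolith_mass_pg: 70
Gephyrocapsa oceanica:
  coccoliths_per_sphere: 18
  coccolith_mass_pg: 8
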