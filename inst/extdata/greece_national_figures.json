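{
  "description": "Published national-scale figures from the reference application of this prioritization workflow to Greece (burned-area record 2001-2023, 500 m analysis grid). Used only as reference values for internal-consistency checks; they are not reproducible at desk scale because they depend on multi-gigabyte versioned external datasets.",
  "burned_any_km2": 15207,
  "repetitive_km2": 2598,
  "repetitive_fraction_printed_pct": 17,
  "steep_km2": 42169,
  "protected_land_km2": 46224,
  "n_protected_areas": 1289,
  "total_priority_km2": 77.25,
  "cell_area_km2": 0.25,
  "n_regions": 14,
  "n_regions_selected": 12
}
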