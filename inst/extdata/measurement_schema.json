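{
  "format": "long CSV, one row per well",
  "columns": {
    "plate_id": "identifier, unique per physical plate",
    "assay": ["H295R", "ER_CALUX", "AR_CALUX"],
    "mode": ["agonist", "antagonist", "none"],
    "row": "plate row letter A-H (A1 origin)",
    "col": "plate column integer 1-12",
    "role": ["h295r_treated", "sham", "standard_curve", "vehicle_control",
             "medium_control", "positive_control"],
    "control": "for control wells: vehicle | medium | forskolin | pfos | prochloraz | menadione (else empty)",
    "curve_role": "for standard_curve wells: vehicle | agonist_only | standard (else empty)",
    "chemical_id": "test-chemical identifier or empty",
    "conc_h295r": "nominal treatment concentration in the H295R well (mol/L after unit normalization)",
    "conc_standard": "standard-compound concentration (mol/L); exactly one of conc_h295r/conc_standard set for non-control wells",
    "conc_unit": "optional: M (default) | uM | IU_per_ml (1 IU/ml = 3.9e-6 M)",
    "bio_rep": "biological replicate 1-3",
    "tech_rep": "technical replicate 1-3 (1-2 on standard curves and positive controls)",
    "rlu_reporter": "luciferase luminescence, arbitrary units, >= 0",
    "rlu_viability": "same-well viability luminescence, arbitrary units, >= 0",
    "supernatant_vol_ul": "microlitres of H295R supernatant transferred",
    "total_vol_ul": "final well volume in microlitres (fold dilution = total/supernatant)"
  }
}
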