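{
  "version": 1,
  "description": "Virtual-species end-to-end benchmark: cool-niche species on a synthetic 100 km x 100 km landscape, uniform +2 degC warming as the future scenario.",
  "landscape": {
    "shape": [100, 100],
    "autocorr_range": 10,
    "variables": ["BIO1", "BIO2", "BIO3", "BIO7", "BIO14", "BIO18", "BIO19"]
  },
  "n_presences": 150,
  "n_pseudo_absences": 1000,
  "buffer_km": 3,
  "suitability_cutoff": 0.5,
  "niche_intercept": 4.0,
  "warming": { "BIO1": 2.0 },
  "species": [
    { "id": "vsp1", "opt_quantile": 0.06, "sharpness": 0.60, "secondary": {} },
    { "id": "vsp2", "opt_quantile": 0.10, "sharpness": 0.50, "secondary": { "BIO14": 0.4 } },
    { "id": "vsp3", "opt_quantile": 0.14, "sharpness": 0.70, "secondary": {} },
    { "id": "vsp4", "opt_quantile": 0.08, "sharpness": 0.45, "secondary": { "BIO18": -0.3 } },
    { "id": "vsp5", "opt_quantile": 0.12, "sharpness": 0.55, "secondary": { "BIO19": 0.3 } }
  ]
}
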