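{
  "score": "Helsinki CT score",
  "source": "Raj R, Siironen J, Skrifvars MB, Hernesniemi J, Kivisaari R. Predicting outcome in traumatic brain injury: development of a novel computerized tomography classification system (Helsinki computerized tomography score). Neurosurgery. 2014;75(6):632-647.",
  "version": "2014-original",
  "note": "If an erratum to the source revises a component weight, update it here; the scoring code reads this table and never hard-codes weights.",
  "range": [-3, 14],
  "weights": {
    "sdh": 2,
    "ich": 2,
    "edh": -3,
    "mass_gt25": 2,
    "ivh": 3,
    "cisterns": {
      "normal": 0,
      "compressed": 1,
      "obliterated": 5
    }
  }
}
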