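# PhenoAge mortality-score coefficients (Levine 2018 ten-term specification).
# Units are the scale each weight expects; values entered in other units must
# be converted at ingest (see convert_units()).
version: levine2018-phenoage-v1
gamma: 0.0076927        # per-month Gompertz rate
horizon_months: 120
intercept: -19.907
inversion:              # risk -> age map: offset + log(scale * (-log(1 - risk))) / rate
  offset: 141.50225
  scale: 0.00553
  rate: 0.090165
markers:
  - name: albumin
    unit: g/L
    weight: -0.0336
  - name: creatinine
    unit: umol/L
    weight: 0.0095
  - name: glucose
    unit: mmol/L
    weight: 0.1953
  - name: crp
    unit: mg/dL
    weight: 0.0954
    transform: log      # CRP enters as natural log of the raw value
  - name: lymphocyte_pct
    unit: percent
    weight: -0.012
  - name: mcv
    unit: fL
    weight: 0.0268
  - name: rdw
    unit: percent
    weight: 0.3306
  - name: alp
    unit: U/L
    weight: 0.00188
  - name: wbc
    unit: 1000 cells/uL
    weight: 0.0554
  - name: chron_age
    unit: years
    weight: 0.0804
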