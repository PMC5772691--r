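# Six-compound anticoagulant rodenticide panel, ESI+ MRM.
# Ranges in ng/mL (blood) or ng/g (faeces dry matter); molar ranges in uM.
# Molar masses are average molecular weights from the molecular formula.
# ion_ratio is the expected qualifier/quantifier response ratio used by the
# synthetic generator and as a fallback for ion-ratio QC.
name: rodenticides6
internal_standard:
  name: warfarin-d5
  molecular_formula: C19H11D5O4
  molar_mass: 313.36
  retention_time: 1.62
  working_concentration_mg_per_L: 0.078
  transitions:
    - {precursor_mz: 314.2, product_mz: 163.1, role: quantifier, cone_voltage: 24, collision_energy: 14}
    - {precursor_mz: 314.2, product_mz: 256.0, role: qualifier,  cone_voltage: 24, collision_energy: 22}
analytes:
  - name: coumatetralyl
    molecular_formula: C19H16O3
    molar_mass: 292.33
    retention_time: 1.86
    ion_ratio: 0.45
    calibration_range: [1.5, 731]
    calibration_range_molar: [0.0050, 2.5]
    transitions:
      - {precursor_mz: 239.1, product_mz: 107.1, role: quantifier, cone_voltage: 40, collision_energy: 32}
      - {precursor_mz: 239.1, product_mz: 91.0,  role: qualifier,  cone_voltage: 30, collision_energy: 28}
  - name: bromadiolone
    molecular_formula: C30H23BrO4
    molar_mass: 527.41
    retention_time: 2.73
    ion_ratio: 0.35
    calibration_range: [2.6, 1319]
    calibration_range_molar: [0.0050, 2.5]
    transitions:
      - {precursor_mz: 511.1, product_mz: 251.2, role: quantifier, cone_voltage: 26, collision_energy: 24}
      - {precursor_mz: 511.1, product_mz: 173.0, role: qualifier,  cone_voltage: 26, collision_energy: 42}
  - name: difenacoum
    molecular_formula: C31H24O3
    molar_mass: 444.52
    retention_time: 2.83
    ion_ratio: 0.55
    calibration_range: [2.2, 1111]
    calibration_range_molar: [0.0050, 2.5]
    transitions:
      - {precursor_mz: 445.3, product_mz: 179.1, role: quantifier, cone_voltage: 30, collision_energy: 32}
      - {precursor_mz: 445.3, product_mz: 257.2, role: qualifier,  cone_voltage: 30, collision_energy: 22}
  - name: flocoumafen
    molecular_formula: C33H25F3O4
    molar_mass: 542.54
    retention_time: 3.17
    ion_ratio: 0.30
    calibration_range: [2.7, 1356]
    calibration_range_molar: [0.0050, 2.5]
    transitions:
      - {precursor_mz: 543.2, product_mz: 159.1, role: quantifier, cone_voltage: 28, collision_energy: 42}
      - {precursor_mz: 543.2, product_mz: 335.2, role: qualifier,  cone_voltage: 28, collision_energy: 24}
  - name: brodifacoum
    molecular_formula: C31H23BrO3
    molar_mass: 523.42
    retention_time: 3.27
    ion_ratio: 0.40
    calibration_range: [2.6, 1309]
    calibration_range_molar: [0.0050, 2.5]
    transitions:
      - {precursor_mz: 525.2, product_mz: 337.1, role: quantifier, cone_voltage: 34, collision_energy: 34}
      - {precursor_mz: 525.2, product_mz: 178.2, role: qualifier,  cone_voltage: 55, collision_energy: 55}
  - name: difethialone
    molecular_formula: C31H23BrO2S
    molar_mass: 539.48
    retention_time: 3.33
    ion_ratio: 0.50
    calibration_range: [2.7, 1349]
    calibration_range_molar: [0.0050, 2.5]
    transitions:
      - {precursor_mz: 539.1, product_mz: 178.1, role: quantifier, cone_voltage: 36, collision_energy: 32}
      - {precursor_mz: 539.1, product_mz: 335.1, role: qualifier,  cone_voltage: 36, collision_energy: 22}
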