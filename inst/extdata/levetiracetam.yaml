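# Packaged compound profile: levetiracetam (LEV)
# Physicochemical / biopharmaceutic inputs plus the one-time absorption
# calibration (permeability scale and segment absorption scale factors).
compound:
  name: levetiracetam
  molecular_weight: 170.21      # g/mol
  log_p: 0.8
  pka: 16.1                     # effectively non-ionizable at physiological pH
  log_d: 0.9
  blood_plasma_ratio: 1.11      # Rbp
  fraction_unbound_plasma: 0.97 # fup
  # The published aqueous solubility is printed with inconsistent units
  # ("1.04 g/mol"); read as 1.04 g/mL.  LEV is freely soluble and
  # dissolution is never solubility-limited at therapeutic doses.
  aqueous_solubility: 1040      # mg/mL
  effective_permeability: 9.6e-06   # cm/s, in vitro (Caco-2-type)
  # One-time in vitro -> in vivo permeability calibration (see vignette):
  # effective human jejunal permeability = permeability_scale * Peff_invitro.
  permeability_scale: 88.0
  # Segment absorption scale factors (dimensionless), declining distally;
  # calibrated once against the adult 1500 mg reference absorption
  # distribution and frozen here.
  asf:
    stomach: 0.0
    duodenum: 1.0
    jejunum1: 0.6667
    jejunum2: 0.3587
    ileum1: 0.0873
    ileum2: 0.0498
    ileum3: 0.0293
    caecum: 0.012
    colon: 0.006
  clearance_plasma: 0.063       # L/h/kg, adult, derived from IV data
  clearance_plasma_literature_adult: 0.0576  # 0.96 mL/min/kg
  clearance_plasma_literature_child: 0.0528  # 0.88 mL/min/kg
  renal_fraction: 0.66
  vd_reference_range: [0.5, 0.7]  # L/kg
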