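# Substance dossier: biphenyl (CAS 92-52-4)
# Same content as biphenyl_dossier(); shipped as the worked example of the
# YAML dossier format read by read_dossier().
name: biphenyl
molecular_weight: 154.21
oel_ppm: 0.2
oel_mgm3: 1.5          # regulatory pairing, stored verbatim (not MW-derived)
slope_factor: 8.2e-3   # per mg/kg-day, hepatic tumours, 2-year mouse study
pods:
  oral_sto:
    value: 23          # mg/kg-day
    pod_type: BMDL
    route: oral
    species: rat
    study_duration_weeks: 104
  inhalation_sto:
    value: 157.75      # mg/m3
    pod_type: LOAEL
    route: inhalation
    species: mouse
    study_duration_weeks: 13
  reproductive:
    value: 20          # mg/kg-day
    pod_type: BMDL
    route: oral
    species: rat
    study_duration_weeks: 9
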