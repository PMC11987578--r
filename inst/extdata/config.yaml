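country: toyland
geo_domain_level: region
has_quality_data: yes
contact_thresholds: [1, 4, 8]
indices:
  anc_readiness:
    items:
      - {code: a, domain: equipment, kind: binary}
      - {code: b, domain: equipment, kind: binary}
      - {code: c, domain: medicines, kind: binary}
      - {code: t, domain: human_resources, kind: proportion}
    country_mask: [a, b, c, t]
  mn_readiness:
    items:
      - {code: a, domain: equipment, kind: binary}
      - {code: c, domain: medicines, kind: binary}
    country_mask: [a, c]
  anc_quality:
    items:
      - {code: q1, domain: examination, kind: binary}
      - {code: q2, domain: counselling, kind: binary}
      - {code: q3, domain: experience, kind: binary}
    country_mask: [q1, q2, q3]
  mn_quality:
    items:
      - {code: q1, domain: examination, kind: binary}
      - {code: q3, domain: experience, kind: binary}
    country_mask: [q1, q3]
intervention_sets:
  anc:
    service: ANC
    interventions: [tt, sp, ifa, bp, urine, blood, deworming]
    country_mask: [tt, ifa, bp]
  mn:
    service: MN
    interventions: [sp, ifa, blood, deworming]
    country_mask: [ifa]
provider_mapping:
  hosp: hospital
  hc: health_centre
  chw: health_centre
  th: UNQUALIFIED
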