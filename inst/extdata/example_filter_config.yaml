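# Default inclusion/exclusion window for a pediatric antineoplastic extract
year_min: 2016
year_max: 2020
causality_whitelist: [certain, probable, possible]
age_min: 0
age_max: 17
atc_prefix: L01
max_plausible_age: 120
dedup_key: report_id
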