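person_id,admission_date,discharge_date,diagnostic_codes
EX03,2008-01-12,2008-01-15,5790;486
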