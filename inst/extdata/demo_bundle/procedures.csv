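person_id,procedure_date,facility_id,intervention_codes,diagnostic_codes
EX01,2007-05-20,FAC001,2OD70,5790;787
EX04,2009-10-05,FAC001,2OD70,787
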