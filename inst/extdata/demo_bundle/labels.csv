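person_id,status,diagnosis_date,marsh_class
EX01,true_positive,2007-05-20,3b
EX02,true_negative,NA,none
EX03,true_negative,NA,none
EX04,true_negative,NA,none
EX05,true_negative,NA,none
EX06,true_negative,NA,none
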