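person_id,service_date,physician_id,diagnostic_code,fee_code
EX01,2007-05-02,FM01,787,A005
EX01,2007-05-20,GI01,787,Z399
EX01,2007-08-14,GI01,5790,A005
EX02,2006-02-10,GI02,5790,A005
EX04,2009-10-05,GI01,787,Z399
EX04,2009-11-20,GI01,5790,A005
EX05,2010-04-18,FM01,5790,A005
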