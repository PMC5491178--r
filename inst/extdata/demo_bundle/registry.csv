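person_id,birth_date,sex,region_flag,eligibility_intervals
EX01,1998-04-10,female,TRUE,1998-04-10/2012-12-31
EX02,2000-11-03,male,TRUE,2000-11-03/2007-06-30;2008-03-01/2012-12-31
EX03,2002-06-21,female,TRUE,2002-06-21/2012-12-31
EX04,1997-01-30,male,TRUE,1997-01-30/2012-12-31
EX05,2004-09-12,female,TRUE,2004-09-12/2012-12-31
EX06,1999-07-04,male,TRUE,1999-07-04/2012-12-31
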