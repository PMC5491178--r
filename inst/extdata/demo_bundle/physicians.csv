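physician_id,specialty
GI01,gastroenterology_pediatric
GI02,gastroenterology_adult
FM01,family_medicine
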