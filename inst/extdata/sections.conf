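# Default section policy: narrative sections are processed, administrative
# sections are excluded. Unknown headers follow the unknown_policy argument.
[include]
findings
impression

[exclude]
reason for exam
referral diagnosis
exam type
signed by

[synonyms]
impressions = impression
finding = findings
reason for examination = reason for exam
electronically signed by = signed by
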