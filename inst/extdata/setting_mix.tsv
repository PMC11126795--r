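# Patient-setting mix of the 200-report study corpus.
# Columns: setting<TAB>n_reports<TAB>n_phrases
setting	n_reports	n_phrases
emergency	63	167
inpatient	73	293
outpatient	64	185
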