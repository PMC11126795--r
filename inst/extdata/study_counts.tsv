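# Summary counts of the four-reviewer manual-coding arm of the study corpus
# (inputs for validation arithmetic; phrase totals are derivable from
# exam_mix.tsv and are not repeated here).
# Columns: name<TAB>value
name	value
n_reviewers	4
phrases_unanimous_no_code	31
phrases_all_reviewers_coded	497
phrases_unanimous_3l	214
phrases_unanimous_4l	174
phrases_unanimous_7l	145
reviewer_mean_hours	6.375
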