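# Polarity trigger table (editable). role is one of {negation, normality}.
# A negation trigger preceding a finding-bearing token anywhere in the
# phrase marks the phrase as a pertinent negative; a phrase made up solely
# of normality terms and stopwords is non-codable.
token,role
no,negation
without,negation
absent,negation
absence,negation
negative,negation
free,negation
unremarkable,negation
resolved,negation
normal,normality
unremarkable,normality
stable,normality
negative,normality
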