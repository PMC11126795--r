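# Clinical synonym table applied during phrase normalization (editable).
# Tokens are matched after case folding and inflection reduction; "to" is
# the canonical vocabulary used by the bundled catalog descriptions.
from,to
bleed,hemorrhage
bleeding,hemorrhage
haemorrhage,hemorrhage
stroke,infarction
infarct,infarction
cva,infarction
ischaemic,ischemic
tumor,neoplasm
tumour,neoplasm
metastasis,neoplasm
metastatic,secondary
narrowing,stenosis
bulge,displacement
protrusion,displacement
clot,thrombosis
stone,calculus
oedema,edema
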