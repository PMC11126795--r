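# Word-class lexicon (editable): whether a token names an anatomic
# structure or a pathologic finding. Pathology tokens are the
# "finding-bearing" nouns used by phrase segmentation (conjunction/comma
# splitting) and by negation scoping; both classes carry matcher weights.
# Tokens are in canonical reduced form.
token,class
neoplasm,pathology
lymphoma,pathology
lipoma,pathology
hemangioma,pathology
meningioma,pathology
nodule,pathology
abscess,pathology
granuloma,pathology
phlebitis,pathology
thrombophlebitis,pathology
thrombosis,pathology
atrophy,pathology
demyelinating,pathology
damage,pathology
encephalopathy,pathology
herniation,pathology
compression,pathology
edema,pathology
myelopathy,pathology
hemorrhage,pathology
hematoma,pathology
infarction,pathology
occlusion,pathology
stenosis,pathology
aneurysm,pathology
stricture,pathology
tonsillitis,pathology
sinusitis,pathology
sialolithiasis,pathology
calculus,pathology
cyst,pathology
malformation,pathology
anomaly,pathology
swelling,pathology
lump,pathology
mass,pathology
effusion,pathology
osteomyelitis,pathology
spondylosis,pathology
displacement,pathology
instability,pathology
lesion,pathology
contusion,pathology
laceration,pathology
fracture,pathology
injury,pathology
disease,pathology
abnormal,pathology
abnormality,pathology
change,pathology
deviated,pathology
ischemic,pathology
brain,anatomy
cerebral,anatomy
cerebellar,anatomy
intracranial,anatomy
intraspinal,anatomy
intracerebral,anatomy
intraventricular,anatomy
subarachnoid,anatomy
subdural,anatomy
skull,anatomy
head,anatomy
scalp,anatomy
face,anatomy
facial,anatomy
occiput,anatomy
meningeal,anatomy
temporal,anatomy
lobe,anatomy
artery,anatomy
carotid,anatomy
vertebral,anatomy
thyroid,anatomy
peritonsillar,anatomy
retropharyngeal,anatomy
parapharyngeal,anatomy
nasal,anatomy
septum,anatomy
maxillary,anatomy
sinus,anatomy
salivary,anatomy
gland,anatomy
duct,anatomy
lymph,anatomy
node,anatomy
neck,anatomy
spine,anatomy
spinal,anatomy
cord,anatomy
vertebra,anatomy
disc,anatomy
intervertebral,anatomy
cervical,anatomy
thoracic,anatomy
lumbar,anatomy
sacrum,anatomy
coccyx,anatomy
occipitoatlantoaxial,anatomy
knee,anatomy
joint,anatomy
kidney,anatomy
appendix,anatomy
musculoskeletal,anatomy
skin,anatomy
subcutaneous,anatomy
tissue,anatomy
canal,anatomy
cerebrospinal,anatomy
vessel,anatomy
venous,anatomy
arachnoid,anatomy
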