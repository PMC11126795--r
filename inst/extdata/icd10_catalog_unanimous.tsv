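# radcoder bundled ICD-10-CM catalog fixture (SYNTHETIC descriptions).
# One row per full-length code on which a four-reviewer panel can agree for
# craniospinal CT/MR impressions. The code list is authoritative; the
# descriptions are hand-written plain-English diagnosis titles in the style
# of the CMS ICD-10-CM order file and are NOT authoritative -- they exist so
# the bag-of-words matcher has a realistic description corpus to index.
# Descriptions are written in canonical (singular, synonym-target) token
# form to mirror phrase normalization.
# Columns: code<TAB>billable<TAB>short_desc<TAB>long_desc
C77.0	1	Secondary neoplasm lymph node head neck	Secondary malignant neoplasm of lymph node of head face and neck
C79.31	1	Secondary neoplasm brain	Secondary malignant neoplasm of brain
C85.89	1	Non-Hodgkin lymphoma other site	Non Hodgkin lymphoma of other extranodal site
D17.0	1	Lipoma head face neck	Benign lipomatous neoplasm lipoma of skin and subcutaneous tissue of head face and neck
D17.79	1	Lipoma other site	Benign lipomatous neoplasm lipoma of other site
D18.09	1	Hemangioma other site	Hemangioma of other site
D32.9	1	Meningioma	Benign meningeal neoplasm meningioma
D49.6	1	Neoplasm unspecified behavior brain	Neoplasm of unspecified behavior of brain
E04.1	1	Thyroid nodule	Nontoxic single thyroid nodule
G06.1	1	Intraspinal abscess	Intraspinal abscess and granuloma
G08	1	Intracranial thrombophlebitis	Intracranial and intraspinal phlebitis and thrombophlebitis venous thrombosis
G31.9	1	Cerebral degeneration	Degenerative disease of nervous system cerebral atrophy volume loss
G37.9	1	Demyelinating disease CNS	Demyelinating disease of central nervous system
G93.1	1	Anoxic brain damage	Anoxic brain damage hypoxic ischemic injury
G93.41	1	Metabolic encephalopathy	Metabolic encephalopathy
G93.5	1	Compression of brain	Compression of brain uncal herniation
G93.6	1	Cerebral edema	Cerebral edema
G93.89	1	Other disorder of brain	Other specified disorder of brain
G95.19	1	Vascular myelopathy	Other vascular myelopathy of spinal cord
I60.9	1	Subarachnoid hemorrhage	Nontraumatic subarachnoid hemorrhage
I61.5	1	Intraventricular hemorrhage	Nontraumatic intracerebral hemorrhage intraventricular
I61.9	1	Intracerebral hemorrhage	Nontraumatic intracerebral hemorrhage unspecified
I62.00	1	Subdural hemorrhage	Nontraumatic subdural hemorrhage hematoma
I62.9	1	Intracranial hemorrhage	Nontraumatic intracranial hemorrhage unspecified
I63.512	1	Infarction left middle cerebral artery	Cerebral infarction due to occlusion of left middle cerebral artery
I63.8	1	Other cerebral infarction	Other cerebral infarction
I63.9	1	Cerebral infarction unspecified	Cerebral infarction unspecified
I65.02	1	Occlusion left vertebral artery	Occlusion and stenosis of left vertebral artery
I65.21	1	Occlusion right carotid artery	Occlusion and stenosis of right carotid artery
I65.22	1	Occlusion left carotid artery	Occlusion and stenosis of left carotid artery
I65.29	1	Occlusion carotid artery unspecified	Occlusion and stenosis of unspecified carotid artery
I67.1	1	Cerebral aneurysm	Cerebral aneurysm nonruptured
I67.83	1	Posterior reversible encephalopathy	Posterior reversible encephalopathy syndrome
I72.6	1	Aneurysm vertebral artery	Aneurysm of vertebral artery
I77.1	1	Stricture of artery	Stricture stenosis of artery
J03.90	1	Acute tonsillitis	Acute tonsillitis unspecified
J32.0	1	Chronic maxillary sinusitis	Chronic maxillary sinusitis
J34.2	1	Deviated nasal septum	Deviated nasal septum
J36	1	Peritonsillar abscess	Peritonsillar abscess
J39.0	1	Retropharyngeal abscess	Retropharyngeal and parapharyngeal abscess
K11.5	1	Sialolithiasis	Sialolithiasis calculus of salivary gland duct
K38.9	1	Disease of appendix	Disease of appendix unspecified
M25.459	1	Effusion knee joint	Effusion of unspecified knee joint
M46.20	1	Osteomyelitis of vertebra	Osteomyelitis of vertebra site unspecified
M47.812	1	Cervical spondylosis	Spondylosis of cervical region
M48.02	1	Spinal stenosis cervical	Spinal canal stenosis cervical region
M48.04	1	Spinal stenosis thoracic	Spinal canal stenosis thoracic region
M48.06	1	Spinal stenosis lumbar	Spinal canal stenosis lumbar region
M50.20	1	Cervical disc displacement	Cervical disc displacement unspecified cervical region
M51.26	1	Lumbar disc displacement	Intervertebral disc displacement lumbar region
M53.2X1	1	Spinal instability occipitoatlantoaxial	Spinal instability occipitoatlantoaxial region
M99.81	1	Biomechanical lesion cervical	Other biomechanical lesion of cervical region
M99.82	1	Biomechanical lesion thoracic	Other biomechanical lesion of thoracic region
M99.83	1	Biomechanical lesion lumbar	Other biomechanical lesion of lumbar region
N20.0	1	Calculus of kidney	Calculus of kidney
Q04.6	1	Congenital cerebral cyst	Congenital cerebral cyst arachnoid
Q28.3	1	Cerebral vascular malformation	Other malformation of cerebral vessel developmental venous anomaly
Q76.49	1	Congenital malformation of spine	Other congenital malformation of spine vertebra
R22.0	1	Localized mass head	Localized swelling mass and lump of head left temporal lobe
R60.0	1	Localized edema	Localized edema of soft tissue
R93.0	1	Abnormal imaging skull head	Abnormal finding on diagnostic imaging of skull and head
R93.7	1	Abnormal imaging musculoskeletal	Abnormal finding on diagnostic imaging of musculoskeletal system
R93.8	1	Abnormal imaging other structure	Abnormal finding on diagnostic imaging of other specified body structure
S00.03XA	1	Contusion of scalp	Contusion of scalp initial encounter
S01.81XA	1	Laceration of head	Laceration of other part of head initial encounter
S02.119A	1	Fracture of occiput	Fracture of occiput skull base initial encounter
S02.92XA	1	Fracture of facial bone	Fracture of facial bone initial encounter
S06.2X9A	1	Diffuse traumatic brain injury	Diffuse traumatic brain injury initial encounter
S12.9XXA	1	Fracture of neck	Fracture of neck cervical vertebra initial encounter
S22.009A	1	Fracture thoracic vertebra	Fracture of unspecified thoracic vertebra initial encounter
S22.080A	1	Wedge compression fracture thoracic	Wedge compression fracture of thoracic vertebra initial encounter
Z96.89	1	Presence of functional implant	Presence of other specified functional implant device
Z98.2	1	Presence of CSF drainage device	Presence of cerebrospinal fluid drainage device ventriculoperitoneal shunt
Z98.890	1	Other postprocedural state	Other specified postprocedural state craniotomy
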