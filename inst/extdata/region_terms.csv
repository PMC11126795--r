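# Keyword-to-body-region map (editable). A catalog entry is tagged with
# every region whose keyword appears among its description tokens; entries
# with no keyword declare no region and score region-neutrally (a
# body-part-nonspecific pathology such as "aneurysm" or "mass" is then
# disambiguated by the exam's body region via the region multipliers).
token,region
brain,head
cerebral,head
cerebellar,head
intracranial,head
intracerebral,head
intraventricular,head
subarachnoid,head
subdural,head
skull,head
head,head
scalp,head
occiput,head
meningeal,head
temporal,head
lobe,head
cerebrospinal,head
craniotomy,head
encephalopathy,head
face,maxillofacial
facial,maxillofacial
maxillary,sinus
nasal,sinus
septum,sinus
sinus,sinus
sinusitis,sinus
carotid,neck
vertebral,neck
thyroid,neck
peritonsillar,neck
retropharyngeal,neck
parapharyngeal,neck
tonsillitis,neck
salivary,neck
neck,neck
cervical,cervical_spine
occipitoatlantoaxial,cervical_spine
thoracic,thoracic_spine
lumbar,lumbar_spine
sacrum,sacrum_coccyx
coccyx,sacrum_coccyx
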