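# Exam-type mix of a 200-report craniospinal CT/MR study corpus, with the
# number of reports, Impression lines, and Impression phrases per exam type.
# Used as sampling weights by the synthetic corpus generator (any n_reports
# is supported; proportions, not exact counts, are reproduced).
# body_region uses the closed vocabulary {head, maxillofacial, sinus, neck,
# cervical_spine, thoracic_spine, lumbar_spine, sacrum_coccyx}.
# Columns: exam_type<TAB>modality<TAB>body_region<TAB>contrast<TAB>n_reports<TAB>n_lines<TAB>n_phrases
exam_type	modality	body_region	contrast	n_reports	n_lines	n_phrases
CT Cervical Spine w/o Contrast	CT	cervical_spine	without	11	18	30
CT Head w/o & w Contrast	CT	head	with_and_without	3	7	9
CT Head w/o Contrast	CT	head	without	73	131	191
CT Lumbar Spine w/o Contrast	CT	lumbar_spine	without	4	11	28
CT Maxillofacial w/o Contrast	CT	maxillofacial	without	6	11	15
CT Sinus w/o Contrast	CT	sinus	without	5	7	7
CT Soft Tissue Neck w Contrast	CT	neck	with	11	22	33
CT Soft Tissue Neck w/o Contrast	CT	neck	without	1	2	5
CT Thoracic Spine w Contrast	CT	thoracic_spine	with	1	3	8
CT Thoracic Spine w/o Contrast	CT	thoracic_spine	without	4	10	16
CTA Angiogram Head	CTA	head	with	1	2	7
CTA Angiogram Head Neck	CTA	head	with	3	9	9
MR Brain Stroke w Contrast	MR	head	with	1	4	11
MR Stroke w/o & w Contrast	MR	head	with_and_without	3	11	23
MR Brain w/o & w Contrast	MR	head	with_and_without	31	53	95
MR Brain w/o Contrast	MR	head	without	6	8	12
MR Cervical Spine w/o Contrast	MR	cervical_spine	without	5	7	20
MR Lumbar Spine w Contrast	MR	lumbar_spine	with	1	1	1
MR Lumbar Spine w/o & w Contrast	MR	lumbar_spine	with_and_without	5	17	27
MR Lumbar Spine w/o Contrast	MR	lumbar_spine	without	11	24	50
MR Sacrum and Coccyx w/o Contrast	MR	sacrum_coccyx	without	1	5	15
MR Neck w/o & w Contrast	MR	neck	with_and_without	1	1	6
MR Thoracic Spine w/o & w Contrast	MR	thoracic_spine	with_and_without	1	2	3
MRA Angio Head w/o Contrast	MRA	head	without	6	7	11
MRA Angio Neck w/o & w Contrast	MRA	neck	with_and_without	5	7	13
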