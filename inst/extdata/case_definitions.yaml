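# Illustrative lifetime case definitions in the shape of Swedish-adapted
# ICD revisions plus ATC drug stems. These placeholder code lists mirror
# the structure of register-based phenotyping configurations; they are not
# a reconstruction of any study's operational supplementary lists.
adhd:
  icd:
    ICD10: [F90]
    ICD9: ['314']
    ICD8: ['308']
    ICD7: ['306']
  atc: [N06BA]
ankylosing_spondylitis:
  icd: {ICD10: [M45], ICD9: ['720'], ICD8: ['712'], ICD7: ['722']}
celiac_disease:
  icd: {ICD10: [K900], ICD9: ['579'], ICD8: ['269'], ICD7: ['286']}
crohns_disease:
  icd: {ICD10: [K50], ICD9: ['555'], ICD8: ['563'], ICD7: ['572']}
graves_disease:
  icd: {ICD10: [E050], ICD9: ['242'], ICD8: ['242'], ICD7: ['252']}
hashimotos_disease:
  icd: {ICD10: [E063], ICD9: ['245'], ICD8: ['245'], ICD7: ['253']}
multiple_sclerosis:
  icd: {ICD10: [G35], ICD9: ['340'], ICD8: ['340'], ICD7: ['345']}
psoriasis:
  icd: {ICD10: [L40], ICD9: ['696'], ICD8: ['696'], ICD7: ['706']}
rheumatoid_arthritis:
  icd: {ICD10: [M05], ICD9: ['714'], ICD8: ['712'], ICD7: ['722']}
sarcoidosis:
  icd: {ICD10: [D86], ICD9: ['135'], ICD8: ['135'], ICD7: ['138']}
sjogrens_syndrome:
  icd: {ICD10: [M350], ICD9: ['710'], ICD8: ['734'], ICD7: ['744']}
systemic_lupus:
  icd: {ICD10: [M32], ICD9: ['710'], ICD8: ['734'], ICD7: ['744']}
type1_diabetes:
  icd: {ICD10: [E10], ICD9: ['250'], ICD8: ['250'], ICD7: ['260']}
  atc: [A10A]
ulcerative_colitis:
  icd: {ICD10: [K51], ICD9: ['556'], ICD8: ['563'], ICD7: ['572']}
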