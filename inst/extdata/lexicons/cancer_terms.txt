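# General cancer terms (hypernyms/hyponyms of "cancer").
# Only three members of the original hand-built 12-term list are documented
# (cancer, tumor, carcinoma); the remainder of this list is a reconstruction
# from common oncology vocabulary and is fully overridable.
cancer
tumor
tumour
neoplasm
carcinoma
sarcoma
leukemia
lymphoma
melanoma
glioma
malignancy
adenocarcinoma
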