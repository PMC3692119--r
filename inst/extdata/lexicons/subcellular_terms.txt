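# Sub-cellular compartments; localization evidence lacking all of these is
# demoted at ranking time.
nucleus
nuclear
nucleolus
cytoplasm
cytoplasmic
cytosol
membrane
mitochondria
mitochondrial
golgi
endoplasmic reticulum
lysosome
peroxisome
chromatin
vesicle
ribosome
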