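# synonym	canonical
prostate cancer	prostate cancer
prostatic carcinoma	prostate cancer
prostate carcinoma	prostate cancer
breast cancer	breast cancer
mammary carcinoma	breast cancer
brain cancer	brain cancer
glioblastoma	brain cancer
meningioma	brain cancer
colon cancer	colon cancer
colorectal cancer	colon cancer
pancreatic cancer	pancreatic cancer
cancer	cancer
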