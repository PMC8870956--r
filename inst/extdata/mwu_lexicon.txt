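# Default multi-word-unit lexicon: domain phrases joined into single
# network nodes (underscore-concatenated), longest match first.
pancreatic cancer
breast cancer
lung cancer
colon cancer
skin cancer
prostate cancer
ovarian cancer
renal cell cancer
basal cell
side effects
side effect
healthy diet
fatty tissue
chest cavity
pain symptoms
medical insurance
health insurance
support group
clinical trial
clinical trials
radiation therapy
chemo therapy
bone marrow
lymph nodes
blood test
blood tests
ct scan
pet scan
family members
daily life
stage four
stage iv
quality of life
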