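patient_id,enumerated,recovered,qc_passed,aberrant
CMMC1,15,5,5,3
CMMC2,16,2,2,2
CMMC3,32,10,6,6
CMMC4,62,23,19,19
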