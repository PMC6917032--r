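# Pharmacogenomic keyword gate: whole-word, case-insensitive matching.
# A trailing * marks a stem matching any word with that prefix.
response
resistance
resistant
metaboli*
efficacy
toxicity
adverse
dose
dosing
dosage
pharmacogen*
genotype
allele
polymorphism
clearance
concentration
addiction
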