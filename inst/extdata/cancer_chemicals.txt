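# Cancer-associated chemical ids (drug-category derived starter set):
# pairs with DNA/protein variants are treated as likely somatic events.
MESH:D000069347
MESH:D000077156
MESH:D013629
MESH:D000077146
MESH:D005472
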