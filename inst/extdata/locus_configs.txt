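[GRCh37]
chromosome = 5
smn1_c840_pos = 70247773
smn2_c840_pos = 69372353
smn1_base = C
smn2_base = T

[GRCh38]
chromosome = 5
smn1_c840_pos = 70951946
smn2_c840_pos = 70076526
smn1_base = C
smn2_base = T

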