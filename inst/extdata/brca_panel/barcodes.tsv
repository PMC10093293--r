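sample	barcode
S01	ATTTTCCG
S02	TGGATGTT
S03	TACAACTT
S04	AGACTAAA
S05	TTGAATCT
S06	AAGTTGCA
S07	ACCTGTTG
S08	ACCCCGGT
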