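sample_id	condition
N1	normal
N2	normal
N3	normal
N4	normal
T1	tumor
T2	tumor
T3	tumor
T4	tumor
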