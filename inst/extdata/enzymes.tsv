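name	site	cut_offset_top	cut_offset_bottom
CfoI	GCG^C	NA	1
HhaI	GCG^C	NA	1
HaeIII	GG^CC	NA	2
AluI	AG^CT	NA	2
MspI	C^CGG	NA	3
RsaI	GT^AC	NA	2
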