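name	sequence	orientation
27F	AGAGTTTGATCMTGGCTCAG	forward
8F	AGAGTTTGATCCTGGCTCAG	forward
63F	CAGGCCTAACACATGCAAGTC	forward
341F	CCTACGGGAGGCAGCAG	forward
519R	GWATTACCGCGGCKGCTG	reverse
907R	CCGTCAATTCCTTTRAGTTT	reverse
1392R	ACGGGCGGTGTGTRC	reverse
1492R	GGTTACCTTGTTACGACTT	reverse
A21F	TTCCGGTTGATCCYGCCGGA	forward
A958R	YCCGGCGTTGAMTCCAATT	reverse
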