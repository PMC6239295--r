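category	subfamily	count
partial	TPSa	15
partial	TPSb	3
partial	TPSe	1
pseudogene	TPSa	8
pseudogene	TPSb	3
pseudogene	TPSc	2
pseudogene	TPSe	1
pseudogene	TPSf	1
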