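>siRNA1_synthetic
AACTTCAGGGTCAGCTTGC
>siRNA2_synthetic
CGTTGTGGCTGTTGTAGTT
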