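# Synthetic stand-in Helper site alignment (see ?helper_sites_synthetic).
# One site per line, followed by its label.
GCCGAAA	synthetic_helper_1
GCCAACT	synthetic_helper_2
GCCGAGA	synthetic_helper_3
GCCAATT	synthetic_helper_4
GCCGACA	synthetic_helper_5
GCCGATT	synthetic_helper_6
GCCAAAA	synthetic_helper_7
GCCGAGT	synthetic_helper_8
GCCGCCA	optimal_reporter_helper
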