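# Synthetic stand-in HMG site alignment (see ?hmg_sites_synthetic).
# One site per line, followed by its label.
GCTTTGATG	synthetic_hmg_1
CCTTTGATG	synthetic_hmg_2
GCTTTGTTC	synthetic_hmg_3
ACTTTGAAG	synthetic_hmg_4
CCTTTGCTC	synthetic_hmg_5
CCTTTGATC	optimal_reporter_hmg
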