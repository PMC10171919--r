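set,u_pfs,u_pd
base,0.84,0.57
astrum,0.94,0.87
correct,0.73,0.59
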