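well,group,f405,f488
A1,background,21,39
A2,background,19,41
B1,EV,102,158
B2,EV,98,163
C1,tald-1,95,210
C2,tald-1,101,221
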