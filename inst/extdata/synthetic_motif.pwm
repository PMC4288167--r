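>SYN10
A	2	2	14	2	2	2	2	14	2	14
C	2	2	2	14	2	2	14	2	2	2
G	2	14	2	2	14	2	2	2	14	2
T	14	2	2	2	2	14	2	2	2	2
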