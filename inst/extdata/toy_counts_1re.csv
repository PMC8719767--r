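group,count
A,1
A,3
A,2
A,5
B,0
B,1
B,0
B,2
C,4
C,7
C,6
C,3
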