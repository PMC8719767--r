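term,estimate,se,z
depth,-0.11982,0.05441,-2.202
sex[male],0.94182,0.17238,5.464
color[brown],0.07987,0.13434,0.595
sex[male]:color[brown],-0.71694,0.17404,-4.119
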