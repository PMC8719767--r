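model,term,estimate,se,z
fultons_k,depth,-0.0163,0.0101,-1.61
fultons_k,sex[male],-0.0739,0.0295,-2.50
fultons_k,color[brown],0.0021,0.0169,0.13
fultons_k,sex[male]:color[brown],0.0561,0.0320,1.75
hsi,depth,0.0207,0.0076,2.74
hsi,sex[male],-0.0132,0.0140,-0.94
hsi,color[brown],0.0413,0.0081,5.10
hsi,sex[male]:color[brown],-0.0130,0.0152,-0.86
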