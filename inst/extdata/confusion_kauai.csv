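class,False killer whale,Rough-toothed dolphin,Short-finned pilot whale 1,Short-finned pilot whale 2,Tt/Pe,Blainville's beaked whale,Cuvier's beaked whale,Stenellid 1,Stenellid 2,Kogia spp.,Noise
False killer whale,242,14,1,0,0,0,0,0,0,0,2
Rough-toothed dolphin,20,4450,38,7,29,0,1,44,9,0,4
Short-finned pilot whale 1,5,9,212,0,4,0,0,0,0,0,0
Short-finned pilot whale 2,2,7,1,24,0,0,0,0,1,0,1
Tt/Pe,0,3,5,0,182,0,0,2,0,0,0
Blainville's beaked whale,0,0,0,1,0,90,0,0,0,0,0
Cuvier's beaked whale,0,0,0,0,0,0,0,0,0,0,0
Stenellid 1,0,4,1,3,8,0,0,1199,0,0,4
Stenellid 2,0,1,0,1,1,0,1,0,179,0,0
Kogia spp.,0,0,0,0,0,0,0,0,0,52,0
Noise,50,12,10,28,2,1,0,9,0,5,1088
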