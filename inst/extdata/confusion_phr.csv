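class,False killer whale,Rough-toothed dolphin,Short-finned pilot whale 1,Short-finned pilot whale 2,Tt/Pe,Blainville's beaked whale,Cuvier's beaked whale,Stenellid 1,Stenellid 2,Kogia spp.,Noise
False killer whale,83,1,2,0,0,0,0,0,0,0,0
Rough-toothed dolphin,11,754,21,1,4,0,0,7,0,2,1
Short-finned pilot whale 1,11,0,58,0,2,0,0,1,0,0,0
Short-finned pilot whale 2,1,1,0,8,1,0,0,0,0,0,0
Tt/Pe,0,33,0,0,254,0,0,20,0,0,0
Blainville's beaked whale,0,0,8,7,2,1986,0,1,0,2,2
Cuvier's beaked whale,0,0,4,7,1,1,531,0,1,0,1
Stenellid 1,0,4,2,0,14,0,0,344,0,0,0
Stenellid 2,0,0,0,0,0,0,0,0,24,0,0
Kogia spp.,0,0,0,0,0,0,0,0,0,13,0
Noise,132,3,4,8,1,3,0,8,0,8,1187
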