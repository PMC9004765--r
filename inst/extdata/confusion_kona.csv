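class,False killer whale,Rough-toothed dolphin,Short-finned pilot whale 1,Short-finned pilot whale 2,Tt/Pe,Blainville's beaked whale,Cuvier's beaked whale,Stenellid 1,Stenellid 2,Kogia spp.,Noise
False killer whale,285,0,25,8,1,0,0,0,0,0,5
Rough-toothed dolphin,1,389,19,14,2,1,0,33,3,0,6
Short-finned pilot whale 1,45,23,885,5,6,2,0,14,2,0,6
Short-finned pilot whale 2,6,3,5,446,0,0,0,2,0,0,1
Tt/Pe,0,14,16,11,161,1,0,3,7,0,0
Blainville's beaked whale,0,0,0,1,1,218,1,3,0,1,2
Cuvier's beaked whale,0,0,0,0,0,0,5,0,0,0,1
Stenellid 1,1,24,19,17,35,3,5,5713,16,1,6
Stenellid 2,0,1,0,1,0,0,0,0,727,0,0
Kogia spp.,0,0,0,0,1,0,0,0,0,249,0
Noise,250,10,25,47,8,15,0,67,19,15,3662
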