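site,class,recall,precision
kona,False killer whale,88.0,48.5
kona,Rough-toothed dolphin,83.1,83.8
kona,Short-finned pilot whale 1,89.6,89.0
kona,Short-finned pilot whale 2,96.3,81.1
kona,Tt/Pe,75.6,74.9
kona,Blainville's beaked whale,96.0,90.8
kona,Cuvier's beaked whale,83.3,45.5
kona,Stenellid 1,97.8,97.9
kona,Stenellid 2,99.7,93.9
kona,Kogia spp.,99.6,93.6
kauai,False killer whale,93.4,75.9
kauai,Rough-toothed dolphin,96.7,98.9
kauai,Short-finned pilot whale 1,92.2,79.1
kauai,Short-finned pilot whale 2,66.7,37.5
kauai,Tt/Pe,94.8,80.5
kauai,Blainville's beaked whale,98.9,98.9
kauai,Cuvier's beaked whale,NA,0
kauai,Stenellid 1,98.4,95.6
kauai,Stenellid 2,97.8,94.7
kauai,Kogia spp.,100,91.2
phr,False killer whale,96.5,34.9
phr,Rough-toothed dolphin,94.1,94.7
phr,Short-finned pilot whale 1,80.6,58.6
phr,Short-finned pilot whale 2,72.7,25.8
phr,Tt/Pe,82.7,91.0
phr,Blainville's beaked whale,98.9,99.8
phr,Cuvier's beaked whale,97.3,100
phr,Stenellid 1,94.5,90.3
phr,Stenellid 2,100,96.0
phr,Kogia spp.,100,52.0
all,False killer whale,91.2,53.3
all,Rough-toothed dolphin,95.3,97.1
all,Short-finned pilot whale 1,89.5,84.9
all,Short-finned pilot whale 2,93.7,74.1
all,Tt/Pe,83.8,82.9
all,Blainville's beaked whale,98.6,98.9
all,Cuvier's beaked whale,97.1,98.5
all,Stenellid 1,97.8,97.1
all,Stenellid 2,99.4,94.1
all,Kogia spp.,99.7,90.2
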