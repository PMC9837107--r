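# electrode positions (mm, RAS)
# reference: FCz
Fp1 -28.412245 87.443899 -3.210754
Fp2 28.412245 87.443899 -3.210754
F7 -74.384223 54.043301 -3.210754
F3 -50.140685 61.918589 46.000000
Fz 0.000000 66.179262 63.908570
F4 50.140685 61.918589 46.000000
F8 74.384223 54.043301 -3.210754
FC5 -78.837638 36.762594 29.952270
FC1 -34.473274 34.473274 78.020425
FC2 34.473274 34.473274 78.020425
FC6 78.837638 36.762594 29.952270
T7 -91.943956 -0.000000 -3.210754
C3 -66.179262 -0.000000 63.908570
Cz 0.000000 0.000000 92.000000
C4 66.179262 0.000000 63.908570
T8 91.943956 0.000000 -3.210754
TP9 -79.299393 -25.765935 -38.880880
CP5 -78.837638 -36.762594 29.952270
CP1 -34.473274 -34.473274 78.020425
CP2 34.473274 -34.473274 78.020425
CP6 78.837638 -36.762594 29.952270
TP10 79.299393 -25.765935 -38.880880
P7 -74.384223 -54.043301 -3.210754
P3 -50.140685 -61.918589 46.000000
Pz 0.000000 -66.179262 63.908570
P4 50.140685 -61.918589 46.000000
P8 74.384223 -54.043301 -3.210754
O1 -28.412245 -87.443899 -3.210754
Oz 0.000000 -91.943956 -3.210754
O2 28.412245 -87.443899 -3.210754
POz 0.000000 -85.889399 32.969851
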