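# 32-channel electrode placement on the 8 x 9 topographic grid
# (10-20 positions of the DEAP montage; 0-based "name row col",
#  row 0 = frontal, col 0 = left)
Fp1 0 3
AF3 0 2
F3  1 2
F7  1 0
FC5 2 1
FC1 2 3
C3  3 2
T7  3 0
CP5 4 1
CP1 4 3
P3  5 2
P7  5 0
PO3 6 3
O1  7 3
Oz  7 4
Pz  5 4
Fp2 0 5
AF4 0 6
Fz  1 4
F4  1 6
F8  1 8
FC6 2 7
FC2 2 5
Cz  3 4
C4  3 6
T8  3 8
CP6 4 7
CP2 4 5
P4  5 6
P8  5 8
PO4 6 5
O2  7 5
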