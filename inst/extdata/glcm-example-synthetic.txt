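# Synthetic 5 x 5 five-level (0-4) worked example for GLCM computation.
# Constructed so the ordered pair (0, 2) occurs exactly twice at d = 1,
# theta = 0 degrees; not taken from any external dataset.
0 2 1 3 4
0 2 4 1 0
2 3 2 2 1
1 4 0 1 3
4 0 1 3 2
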