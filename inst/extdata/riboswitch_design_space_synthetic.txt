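# Theophylline riboswitch design space (transcriptional OFF switch).
# SYNTHETIC RECONSTRUCTION from the published construction protocol
# (Wachsmuth et al. 2013, NAR 41:2541-2551): TCT8-4 theophylline aptamer,
# spacer of 6-20 nt, 10-21 nt complementary to the aptamer 3' end, and an
# 8-U stretch. The first 10 complement nucleotides (reverse complement of
# the aptamer 3' end) are shared by all constructs and therefore fixed;
# longer complements extend into the variable region that follows them.
# Structure constraints: 10 bp terminator stem core, unpaired U-stretch.
# Total length bounds: 42 + [6,20] + [10,21] + 8 = [66, 91] nt.
sequence: AAGUGAUACCAGCAUCGUCUUGAUGCCCUUGGCAGCACUUCA?*UGAAGUGCUG?*UUUUUUUU
structure: ????????????????????????????????((((((((((?*))))))))))?*........
min_length: 66
max_length: 91
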