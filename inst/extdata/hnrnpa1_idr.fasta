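>hnRNPA1_IDR first 135 residues of the hnRNPA1 IDR (LCD of isoform A1-A)
MASASSSQRGRSGSGNFGGGRGGGFGGNDNFGRGGNFSGRGGFGGSRGGGGYGGSGDGYN
GFGNDGSNFGGGGSYNDFGNYNNQSSNFGPMKGGNFGGRSSGPYGGGGQYFAKPRNQGGY
GGSSSSSSYGSGRRF
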