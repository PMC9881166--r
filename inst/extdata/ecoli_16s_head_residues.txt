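# Operational SSU head definition, E. coli 16S rRNA numbering.
# The head is taken as the 3' major domain (helices h28-h43).
# This is a fixed, versioned residue list used to partition matched SSU
# residues into head and body; see package documentation.
921-1396
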