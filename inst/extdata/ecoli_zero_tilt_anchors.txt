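# Operational zero-tilt anchor residue sets, E. coli 16S numbering.
# body_anchor: 16S helix h44 (the body zero-tilt direction points from the
#   body rotation axis toward the h44 centroid, projected perpendicular to
#   the axis).
# head_anchor_from / head_anchor_to: proxies for the E-site and A-site
#   codon regions; the head zero-tilt direction is the E->A vector projected
#   perpendicular to the head rotation axis.
body_anchor	1404-1496
head_anchor_from	690-696
head_anchor_to	1491-1498
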