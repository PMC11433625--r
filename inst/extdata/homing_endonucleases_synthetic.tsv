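# Homing endonucleases with long recognition sites (I-CeuI, I-SceI,
# PI-PspI, PI-SceI). Their sites are so long that they essentially never
# occur in an ITS amplicon, so a database build excludes them from the
# panel. Sites transcribed from REBASE; cut offsets are placed inside the
# site for length bookkeeping only (these enzymes never cut here), hence
# the "synthetic" label.
I-CeuI	TAACTATAACGGTCCTAA^GGTAGCGA
I-SceI	TAGGGATAA^CAGGGTAAT
PI-PspI	TGGCAAACAGCTATTAT^GGGTATTATGGGT
PI-SceI	ATCTATGTCGGGTGC^GGAGAAAGAGGTAAT
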