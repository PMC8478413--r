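# cas12array species registry
#
# Plain-text key=value config, one [section] per Cas variant. Edit or copy
# this file and pass its path to get_species_profile()/cmd_design() to
# override any default.
#
# mature_repeat: the post-processing direct repeat retained on the gRNA
#   5' end. Lb/As mature repeats are the standard literature sequences.
# full_separator: the AT-rich ~16-nt fragment of the pre-processing repeat
#   excised during maturation. The curated per-species separator sequences
#   live in supplementary species records not bundled here; the entries
#   below are SYNTHETIC placeholders consistent with the conserved 5'
#   GTYTA motif and the AT-rich 3' terminus from which each synSeparator
#   derives. Replace with curated sequences before relying on them.
# default_synseparator: the short 3'-terminal fragment of the natural
#   separator used as the default synthetic separator.

[LbCas12a]
mature_repeat = AATTTCTACTAAGTGTAGAT
full_separator = GTCTAAGAACTTAAAT
default_synseparator = AAAT
provenance = mature repeat: literature standard (LbCpf1); full separator: synthetic placeholder (GTYTA 5' motif, AAAT 3' terminus); synSeparator AAAT: 3' end of the natural Lb separator

[AsCas12a]
mature_repeat = AATTTCTACTCTTGTAGAT
full_separator = GTTTAAGTACTATTTT
default_synseparator = TTTT
provenance = mature repeat: literature standard (AsCpf1); full separator: synthetic placeholder (GTYTA 5' motif, TTTT 3' terminus); synSeparator TTTT: 3' end of the natural As separator
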