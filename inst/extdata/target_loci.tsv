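# Ten-locus insertion-trap panel: amplicon lengths (BssSI-digested, bp)
# and chromosome of each target. x_linked loci are present in half of sperm.
name	chromosome	amplicon_length_bp	x_linked
DMD	X	4909	TRUE
F9	X	5552	TRUE
CHM	X	5678	TRUE
CYBB	X	5160	TRUE
RP2	X	4774	TRUE
HBB	11	5006	FALSE
FKTN	9	5019	FALSE
APC	5	5417	FALSE
HOXD	2	4286	FALSE
MHC2	6	5018	FALSE
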