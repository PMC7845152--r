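# Default adapters searched for in reads, tab separated name / sequence.
# These are the standard published Illumina/SOLiD adapter prefixes used
# by FastQC-compatible tools.
Illumina Universal Adapter	AGATCGGAAGAG
Illumina Small RNA 3' Adapter	TGGAATTCTCGG
Illumina Small RNA 5' Adapter	GATCGTCGGACT
Nextera Transposase Sequence	CTGTCTCTTATA
SOLID Small RNA Adapter	CGCCTTGGCCGT
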