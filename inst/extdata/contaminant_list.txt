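# Default contaminants screened against overrepresented sequences,
# tab separated name / sequence.
# This is a curated subset of widely published Illumina library adapter
# and PCR primer sequences (the usual sources of overrepresentation in
# Illumina libraries); users can supply their own list with the same
# name<TAB>sequence dialect via the -c/--contaminants option.
Illumina Single End Adapter 1	GATCGGAAGAGCTCGTATGCCGTCTTCTGCTTG
Illumina Single End Adapter 2	CAAGCAGAAGACGGCATACGAGCTCTTCCGATCT
Illumina Single End PCR Primer 1	AATGATACGGCGACCACCGAGATCTACACTCTTTCCCTACACGACGCTCTTCCGATCT
Illumina Single End PCR Primer 2	CAAGCAGAAGACGGCATACGAGCTCTTCCGATCT
Illumina Single End Sequencing Primer	ACACTCTTTCCCTACACGACGCTCTTCCGATCT
Illumina Paired End Adapter 1	ACACTCTTTCCCTACACGACGCTCTTCCGATCT
Illumina Paired End Adapter 2	GATCGGAAGAGCGGTTCAGCAGGAATGCCGAG
Illumina Paired End PCR Primer 1	AATGATACGGCGACCACCGAGATCTACACTCTTTCCCTACACGACGCTCTTCCGATCT
Illumina Paired End PCR Primer 2	CAAGCAGAAGACGGCATACGAGATCGGTCTCGGCATTCCTGCTGAACCGCTCTTCCGATCT
Illumina Paired End Sequencing Primer 1	ACACTCTTTCCCTACACGACGCTCTTCCGATCT
Illumina Paired End Sequencing Primer 2	CGGTCTCGGCATTCCTGCTGAACCGCTCTTCCGATCT
Illumina Multiplexing PCR Primer 1.01	AATGATACGGCGACCACCGAGATCTACACTCTTTCCCTACACGACGCTCTTCCGATCT
Illumina Multiplexing PCR Primer 2.01	GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT
Illumina Multiplexing Read 1 Sequencing Primer	ACACTCTTTCCCTACACGACGCTCTTCCGATCT
Illumina Multiplexing Read 2 Sequencing Primer	GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT
TruSeq Universal Adapter	AATGATACGGCGACCACCGAGATCTACACTCTTTCCCTACACGACGCTCTTCCGATCT
TruSeq Adapter Index 1	GATCGGAAGAGCACACGTCTGAACTCCAGTCACATCACGATCTCGTATGCCGTCTTCTGCTTG
Nextera Transposase Sequence Read 1	TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG
Nextera Transposase Sequence Read 2	GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG
Illumina Small RNA RT Primer	CAAGCAGAAGACGGCATACGA
Illumina 5p RNA Adapter	GTTCAGAGTTCTACAGTCCGACGATC
Illumina RNA PCR Primer	AATGATACGGCGACCACCGAGATCTACACGTTCAGAGTTCTACAGTCCGA
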