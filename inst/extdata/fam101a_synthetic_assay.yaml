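# Packaged default assay: six-CpG cardiomyocyte marker amplicon.
# The primer portions and adapter overhangs are the published assay
# primers.  The 90 bp reference insert is a SYNTHETIC stand-in for the
# unpublished genomic sequence of chr12:124,207,916-124,208,005: its
# bisulfite-converted primer footprints match the published primers and
# it carries 6 CpGs plus 6 non-CpG cytosines at realistic spacing.
name: fam101a_synthetic
reference_seq: TATGGCTTGGTAATTCATTTAGAGATTACGGTTCAGTTACGTTCGGACGTTAGTCGGTTCATTACGTATTTACTTGTGGGACTTGTATTT
locus_label: "chr12:124,207,916-124,208,005"
cpg_offsets: [28, 39, 43, 47, 54, 64]
primer_fwd: TATGGTTTGGTAATTTATTTAGAG
primer_rev: AAATACAAATCCCACAAATAAA
adapter_fwd: TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG
adapter_rev: GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG
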