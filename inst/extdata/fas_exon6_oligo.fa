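>FAS_exon6_doped_oligo lowercase = doped exon, uppercase = invariant intronic flanks
TGTCCAATGTTCCAACCTACAGgatccagatctaacttggggtggctttgtcttcttcttttgccaattccactaattgtttgggGTAAGTTCTTGCTTTGTTCAAACTGCAGATTGAAATAACTTGGGAAGTAG
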