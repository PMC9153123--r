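"codon","class"
"GCA","optimal"
"GCC","non-optimal"
"GCG","non-optimal"
"GCT","non-optimal"
"TGC","optimal"
"TGT","non-optimal"
"GAC","optimal"
"GAT","non-optimal"
"GAA","optimal"
"GAG","non-optimal"
"TTC","optimal"
"TTT","non-optimal"
"GGA","optimal"
"GGC","non-optimal"
"GGG","non-optimal"
"GGT","non-optimal"
"CAC","optimal"
"CAT","non-optimal"
"ATA","optimal"
"ATC","non-optimal"
"ATT","non-optimal"
"AAA","optimal"
"AAG","non-optimal"
"CTA","optimal"
"CTC","non-optimal"
"CTG","non-optimal"
"CTT","non-optimal"
"TTA","non-optimal"
"TTG","non-optimal"
"AAC","optimal"
"AAT","non-optimal"
"CCA","optimal"
"CCC","non-optimal"
"CCG","non-optimal"
"CCT","non-optimal"
"CAA","optimal"
"CAG","non-optimal"
"AGA","optimal"
"AGG","non-optimal"
"CGA","non-optimal"
"CGC","non-optimal"
"CGG","non-optimal"
"CGT","non-optimal"
"AGC","optimal"
"AGT","non-optimal"
"TCA","optimal"
"TCC","non-optimal"
"TCG","non-optimal"
"TCT","non-optimal"
"ACA","optimal"
"ACC","non-optimal"
"ACG","non-optimal"
"ACT","non-optimal"
"GTA","optimal"
"GTC","non-optimal"
"GTG","non-optimal"
"GTT","non-optimal"
"TAC","optimal"
"TAT","non-optimal"
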