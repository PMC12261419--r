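rank	uniprot_taxa	included_taxa	proteomes
species	13187	403	5043
genus	8926	960	11490
family	2215	519	9519
order	899	292	7169
class	373	139	4298
phylum	274	91	2942
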