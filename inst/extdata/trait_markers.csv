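trait,gene,marker_id,chrom,pos_bp,negative_allele,positive_allele,negative_trait,positive_trait,use,hap_index,favorable_haplotypes,unfavorable_haplotypes,class_map,note
Grain size,GS3,chr03:16733441,chr03,16733441,G,T,Short,Long,single,1,T,G,,
Bacterial leaf blight resistance,xa5,chr05:437499,chr05,437499,T,A,Susceptible,Resistant,single,1,A,T,,
Bacterial leaf blight resistance,Xa7,chr06:27275515,chr06,27275515,G,A,Susceptible,Resistant,haplotype,1,AAC,GCA,,
Bacterial leaf blight resistance,Xa7,chr06:27627615,chr06,27627615,C,A,Susceptible,Resistant,haplotype,2,AAC,GCA,,
Bacterial leaf blight resistance,Xa7,chr06:27761109,chr06,27761109,A,C,Susceptible,Resistant,haplotype,3,AAC,GCA,,
Bacterial leaf blight resistance,xa13,chr08:26448560,chr08,26448560,T,G,Susceptible,Resistant,haplotype,1,GGC,TAT,,
Bacterial leaf blight resistance,xa13,chr08:26709228,chr08,26709228,A,G,Susceptible,Resistant,haplotype,2,GGC,TAT,,
Bacterial leaf blight resistance,xa13,chr08:26898822,chr08,26898822,T,C,Susceptible,Resistant,haplotype,3,GGC,TAT,,
Bacterial leaf blight resistance,Xa4,chr11:27603799,chr11,27603799,C,A,Susceptible,Resistant,single,1,A,C,,
Bacterial leaf blight resistance,Xa21,chr11:21190115,chr11,21190115,C,T,Susceptible,Resistant,single,1,T,C,,
Bacterial leaf blight resistance,Xa23,chr11:22162729,chr11,22162729,C,T,Susceptible,Resistant,haplotype,1,TTA,CCG,,
Bacterial leaf blight resistance,Xa23,chr11:22453819,chr11,22453819,C,T,Susceptible,Resistant,haplotype,2,TTA,CCG,,
Bacterial leaf blight resistance,Xa23,chr11:23231455,chr11,23231455,G,A,Susceptible,Resistant,haplotype,3,TTA,CCG,,
Rice tungro spherical virus resistance,rstv,chr07:22119347,chr07,22119347,A,G,Susceptible,Resistant,single,1,G,A,,
Submergence tolerance,sub1,chr09:5922125,chr09,5922125,C,T,Susceptible,Tolerant,haplotype,1,TAG,CGC,,
Submergence tolerance,sub1,chr09:6252407,chr09,6252407,G,A,Susceptible,Tolerant,haplotype,2,TAG,CGC,,
Submergence tolerance,sub1,chr09:6913547,chr09,6913547,C,G,Susceptible,Tolerant,haplotype,3,TAG,CGC,,
Gelatinization temperature,ALK,chr06:6752756,chr06,6752756,A,G,Low-GT,High-GT,single,1,G,A,,
Apparent amylose content,Wx,chr06:1765761,chr06,1765761,G,T,,,haplotype,1,,,GAC=high;GAT=high;GCC=intermediate;TAC=low;TCC=low,high-class haplotypes reported as both GAC and GAT in the source material; both are encoded
Apparent amylose content,Wx,chr06:1768006,chr06,1768006,A,C,,,haplotype,2,,,GAC=high;GAT=high;GCC=intermediate;TAC=low;TCC=low,
Apparent amylose content,Wx,chr06:1768998,chr06,1768998,C,T,,,haplotype,3,,,GAC=high;GAT=high;GCC=intermediate;TAC=low;TCC=low,
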