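chrom	start	end
chr1	121535435	124535434
chr2	92326172	95326171
chr3	90504855	93504854
chr4	49660118	52660117
chr5	46405642	49405641
chr6	58830167	61830166
chr7	58054332	61054331
chr8	43838888	46838887
chr9	47367680	50367679
chr10	39254936	42254935
chr11	51644206	54644205
chr12	34856695	37856694
chr13	16000001	19000000
chr14	16000001	19000000
chr15	17000001	20000000
chr16	35335802	38335801
chr17	22263007	25263006
chr18	15460899	18460898
chr19	24681783	27681782
chr20	26369570	29369569
chr21	11288130	14288129
chr22	13000001	16000000
chrX	58632013	61632012
chrY	10104554	13104553
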