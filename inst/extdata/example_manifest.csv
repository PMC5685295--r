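probe_id,gene_symbol,chrom,pos,gene_region,island_relation,island_id
cg0001,PRDM14,chr8,70963000,TSS1500,Island,CGI_PRDM14_TSS
cg0002,PRDM14,chr8,70963120,TSS200,Island,CGI_PRDM14_TSS
cg0003,PRDM14,chr8,70963400,FirstExon,Island,CGI_PRDM14_TSS
cg0004,PRDM14,chr8,70961500,TSS1500,N_Shore,
cg0005,PRDM14,chr8,70968000,Body,Island,CGI_PRDM14_BODY
cg0006,PRDM14,chr8,70985000,Intergenic,OpenSea,
cg0007,KLF4,chr9,110252000,TSS200,Island,CGI_KLF4_TSS
cg0008,KLF4,chr9,110252210,UTR5,Island,CGI_KLF4_TSS
cg0009,KLF4,chr9,110249500,TSS1500,N_Shelf,
cg0010,KLF4;KLF4P1,chr9,110254000,Body,S_Shore,
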