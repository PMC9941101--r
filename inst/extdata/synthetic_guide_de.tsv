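snorna	log2fc	padj	source
SNORD90	1.2	0.001	smallRNAseq
SNORD66	0.9	0.004	smallRNAseq
SNORD50A	0.8	0.01	smallRNAseq
SNORD68	0.7	0.03	smallRNAseq
SNORD102	0.6	0.2	smallRNAseq
SNORD114-14	-1.5	0.002	smallRNAseq
SNORD93	0.3	0.4	smallRNAseq
SNORD98	0.25	0.35	smallRNAseq
SNORA47	1.1	5e-04	smallRNAseq
SNORA33	0.9	0.01	smallRNAseq
SNORA22	0.1	0.8	smallRNAseq
SNORA37	0.8	0.02	smallRNAseq
SNORA30	0.05	0.9	smallRNAseq
SNORA63	0.4	0.04	smallRNAseq
SNORA7A	0.3	0.3	smallRNAseq
SNORA54	0.7	0.015	smallRNAseq
SNORA31	0.35	0.25	smallRNAseq
SNORA2A	0.45	0.12	smallRNAseq
SNORD90	1.05	0.01	qPCR
SNORD66	0.85	0.02	qPCR
SNORD114-14	-1.2	0.01	qPCR
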