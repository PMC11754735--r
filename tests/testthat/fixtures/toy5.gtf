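chr1	toy	gene	1001	2000	.	+	.	gene_id "TG1"; gene_type "protein_coding";
chr1	toy	gene	12001	15000	.	-	.	gene_id "TG2"; gene_type "protein_coding";
chr1	toy	gene	30001	31000	.	+	.	gene_id "TG3"; gene_type "lincRNA";
chr2	toy	gene	501	4000	.	+	.	gene_id "TG4"; gene_type "protein_coding";
chr2	toy	gene	20001	22000	.	-	.	gene_id "TG5"; gene_type "protein_coding";
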