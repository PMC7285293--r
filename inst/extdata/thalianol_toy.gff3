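##gff-version 3
# Synthetic toy annotation mirroring the gene composition of the Arabidopsis
# thalianol triterpene cluster: an acyltransferase (unassigned under the
# five-family catalog), thalianol synthase (TPS-class OSC) and three P450s.
chr5	toy	gene	100000	102000	.	+	.	ID=ACT;product=BAHD acyltransferase
chr5	toy	gene	105000	107000	.	-	.	ID=THAH;product=thalian-diol hydroxylase cytochrome P450 708A2
chr5	toy	gene	110000	112000	.	+	.	ID=THAS;product=thalianol synthase oxidosqualene cyclase
chr5	toy	gene	116000	118000	.	-	.	ID=THAD;product=thalian-diol desaturase cytochrome P450 705A5
chr5	toy	gene	121000	123000	.	+	.	ID=CYP705A12;product=cytochrome P450 705A12
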