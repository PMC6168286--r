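##gff-version 3
##sequence-region c1 1 30000
##sequence-region c2 1 20000
c2	toy	gene	1001	2500	.	+	.	ID=gA;Name=gA
c2	toy	gene	4001	6000	.	-	.	ID=gB;Name=gB
c2	toy	gene	9001	11000	.	+	.	ID=gC;Name=gC
c1	toy	gene	16001	18000	.	+	.	ID=gD;Name=gD
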