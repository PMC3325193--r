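gene	start_codon	internal_stops	terminal_codon
sdh4	ACG	-	CAA
atp9	ATG	-	CAA
rps13	ACG	-	CGA
nad9	ACG	-	CAA
nad1	ACG	TAA	CGA
cox1	ACG	-	TAA
nad5	ACG	TAA	CAA
rps12	ATG	TAA	TAA
rps2	ATG	-	CAA
rpl6	ATG	-	CAA
cob	ATG	TAG	TAA
cox3	ATG	-	CAA
rpl16	GTG	-	TAA
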