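# Per-transition-state free-energy barriers (kcal/mol) for the best-ranked
# polymer-drug conjugates (acylation) and polymeric carriers (deacylation)
# hydrolysed by human carboxylesterase 2. provenance: FEL = free-energy
# landscape, PES = potential-energy scan.
id	phase	ts	dg	provenance
2a	acylation	TS1	22.0	FEL
2a	acylation	TS2	22.2	FEL
4a	acylation	TS1	22.3	FEL
4a	acylation	TS2	19.4	FEL
4b	acylation	TS1	20.2	FEL
4b	acylation	TS2	19.1	FEL
6a	acylation	TS1	19.9	FEL
6a	acylation	TS2	20.8	FEL
6b	acylation	TS1	18.3	FEL
6b	acylation	TS2	21.6	FEL
6c	acylation	TS1	22.7	FEL
6c	acylation	TS2	23.7	FEL
11a	deacylation	TS3	16.4	FEL
11a	deacylation	TS4	20.1	FEL
11b	deacylation	TS3	18.2	PES
11b	deacylation	TS4	19.8	PES
11c	deacylation	TS3	15.2	PES
11c	deacylation	TS4	21.8	PES
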