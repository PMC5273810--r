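object_name	gene_ids	fold_change	A	n	R	N	E	ratio	z	p	p_tol
IRF9	IRF9	-1.7	7	102	60	26494	0.231	30.3	14.1	3.32e-09	1e-11
STAT1	STAT1	-2.6	22	102	575	26494	2.214	9.9	13.5	4.04e-16	1e-18
Fc gamma RII beta	FCGR2B	-1.4	2	102	35	26494	0.135	14.8	5.1	0.0080	1e-4
PKC-delta	PRKCD	-1.7	8	102	386	26494	1.486	5.4	5.4	0.0001	1e-4
PSMB9	PSMB9	-1.7	3	102	38	26494	0.146	20.5	7.5	0.0004	1e-4
PSMB8(LMP7)	PSMB8	-1.6	2	102	30	26494	0.115	17.3	5.6	0.0059	1e-4
SHP-1	PTPN6	-1.9	5	102	200	26494	0.770	6.5	4.8	0.0010	1e-4
MxA	MX1;MX2	-3.5;-2.2	3	102	57	26494	0.219	13.7	6.0	0.0013	1e-4
IFIT1	IFIT1	-4.0	4	102	15	26494	0.058	69.3	16.4	2.74e-07	1e-9
TOM34	TOMM34	-1.6	2	102	21	26494	0.081	24.7	6.8	0.0029	1e-4
RIG-G	IFIT3	-3.5	6	102	66	26494	0.254	23.6	11.4	2.11e-07	1e-9
C1 inhibitor	SERPING1	-4.0	2	102	23	26494	0.089	22.6	6.4	0.0035	1e-4
p40-phox	NCF4	-1.8	2	102	23	26494	0.089	22.6	6.4	0.0035	1e-4
TAP1 (PSF1)	TAP1	-1.6	4	102	51	26494	0.196	20.4	8.6	4.5e-05	1e-6
ISG15	ISG15	-4.2	8	102	256	26494	0.986	8.1	7.1	6.83e-06	1e-8
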