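motif_type	aa5	aa_last	wA	wC	wG	wU	provenance
P1	N	D	0.05	0.2	0.05	0.7	literature_canonical
P1	N	N	0.05	0.46	0.05	0.44	literature_canonical
P1	N	S	0.15	0.75	0.02	0.08	literature_canonical
P1	T	D	0.05	0.03	0.85	0.07	literature_canonical
P1	T	N	0.85	0.05	0.07	0.03	literature_canonical
P1	S	N	0.7	0.15	0.05	0.1	literature_canonical
P1	S	D	0.1	0.05	0.7	0.15	literature_canonical
L1	N	D	0.05	0.2	0.05	0.7	literature_canonical
L1	N	N	0.05	0.46	0.05	0.44	literature_canonical
L1	N	S	0.15	0.75	0.02	0.08	literature_canonical
L1	T	D	0.05	0.03	0.85	0.07	literature_canonical
L1	T	N	0.85	0.05	0.07	0.03	literature_canonical
L1	S	N	0.7	0.15	0.05	0.1	literature_canonical
L1	S	D	0.1	0.05	0.7	0.15	literature_canonical
S1	N	D	0.05	0.2	0.05	0.7	literature_canonical
S1	N	N	0.05	0.46	0.05	0.44	literature_canonical
S1	N	S	0.15	0.75	0.02	0.08	literature_canonical
S1	T	D	0.05	0.03	0.85	0.07	literature_canonical
S1	T	N	0.85	0.05	0.07	0.03	literature_canonical
S1	S	N	0.7	0.15	0.05	0.1	literature_canonical
S1	S	D	0.1	0.05	0.7	0.15	literature_canonical
P2	N	D	0.05	0.2	0.05	0.7	literature_canonical
P2	N	N	0.05	0.46	0.05	0.44	literature_canonical
P2	N	S	0.15	0.75	0.02	0.08	literature_canonical
P2	T	D	0.05	0.03	0.85	0.07	literature_canonical
P2	T	N	0.85	0.05	0.07	0.03	literature_canonical
P2	S	N	0.7	0.15	0.05	0.1	literature_canonical
P2	S	D	0.1	0.05	0.7	0.15	literature_canonical
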