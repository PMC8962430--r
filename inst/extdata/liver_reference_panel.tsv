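accession	gene	group	ba_mean	ba_sem	panel_only
Q9JJJ3	Aqp9	basolateral	3.72	0.02	no
P14246	Slc2a2	basolateral	3.19	0.02	no
Q9R1S7	Abcc6	basolateral	3.02	0.01	no
P58735	Slc26a1	basolateral	2.93	0.01	no
Q9QXZ6	Slco1a1	basolateral	2.87	0.01	no
P31649	Slc6a13	basolateral	2.75	0.04	no
O08705	Slc10a1	basolateral	2.70	0.01	no
P53986	Slc16a1	basolateral	2.69	0.01	no
P41233	Abca1	basolateral	2.66	0.01	no
O70451	Slc16a7	basolateral	2.63	0.09	no
Q3T9X0	Slc2a9	basolateral	2.50	0.01	no
P14094	Atp1b1	basolateral	2.36	0.00	no
Q8VDN2	Atp1a1	basolateral	2.23	0.00	no
Q9QZW0	Atp11c	basolateral	2.22	0.00	no
Q9JJL3	Slco1b2	basolateral	2.21	0.01	no
O08966	Slc22a1	basolateral	2.20	0.04	no
Q9JIM1	Slc29a1	basolateral	2.11	0.01	no
Q9Z2J0	Slc23a1	basolateral	2.03	0.05	no
Q8BXB6	Slco2b1	basolateral	1.94	0.01	no
Q9DCP2	Slc38a3	basolateral	1.92	0.01	no
Q9Z0E8	Slc22a5	basolateral	1.86	0.06	no
B2RX12	Abcc3	basolateral	1.71	0.00	no
P97370	Atp1b3	basolateral	1.69	0.01	no
NA	Tubulins	both	NA	NA	yes
O09044	Snap23	both	NA	NA	yes
O88792	F11r	both	NA	NA	yes
P09055	Itgb1	both	NA	NA	yes
P70704	Atp8b1	apical	NA	NA	yes
O70228	Atp9a	apical	NA	NA	yes
Q99PE8	Abcg5	apical	0.596	0.011	no
Q8VI47	Abcc2	apical	0.564	0.001	no
Q9DBM0	Abcg8	apical	0.520	0.007	no
Q9QY30	Abcb11	apical	0.492	0.000	no
Q7TMS5	Abcg2	apical	0.483	0.001	no
P21440	Abcb4	apical	0.464	0.001	no
P09242	Alpl	apical	0.454	0.004	no
P97449	Anpep	apical	0.406	0.001	no
P28843	Dpp4	apical	0.301	0.000	no
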