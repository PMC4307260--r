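kingdom	group	species	I.1	I.2	I.3	I.4	I.5	I.6	I.7	I.8	I.9	I.10	I.11	I.12	I.13	I.14	II.1	II.2	II.3	II.4	II.5	II.6	II.7	II.8	II.9	II.10	II.11	III
Animal	NA	Culex quinquefasciatus	7	1	6	0	0	0	0	0	0	0	0	1	0	0	1	0	0	0	1	1	0	1	0	1	2	2
Bacteria	NA	Escherichia coli	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	1	1	3
Fungus	NA	Penicillium marneffei	4	0	3	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	1	1	0	1	0	1	0	2
Fungus	NA	Aspergillus nidulans	4	0	5	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	1	1	0	1	0	1	0	2
Plant	Gymnospermae	Pinus taeda	0	0	0	0	0	0	0	0	2	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	2
Plant	Gymnospermae	Pinus pinaster	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1
Plant	Gymnospermae	Pseudotsuga menziesii	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	5
Plant	Algae	Chlamydomonas reinhardtii	16	6	4	5	0	0	0	0	0	0	4	2	0	0	0	0	0	0	3	3	0	2	0	5	3	13
Plant	Pteridophyta	Selaginella moellendorffii	83	14	18	2	0	3	0	4	8	7	8	5	0	2	0	0	5	9	8	5	1	8	2	29	18	49
Plant	Dicotyledoneae	Glycine max	85	11	7	1	0	3	0	13	11	1	5	4	0	4	0	0	14	12	16	15	2	11	5	29	31	53
Plant	Dicotyledoneae	Populus trichocarpa	65	5	7	1	0	1	0	4	4	9	3	3	0	1	0	0	6	6	7	6	1	4	1	20	17	50
Plant	Dicotyledoneae	Arabidopsis thaliana	36	5	6	1	0	2	0	2	2	6	2	3	0	1	0	0	4	3	5	3	1	1	0	11	12	13
Plant	Dicotyledoneae	Arabidopsis lyrata	34	8	21	0	45	0	0	0	0	2	0	7	0	0	0	0	0	0	8	8	0	1	0	8	8	8
Plant	Dicotyledoneae	Vitis vinifera	57	4	5	1	0	1	0	9	2	4	2	2	0	2	0	0	3	4	4	4	1	2	1	9	13	41
Plant	Dicotyledoneae	Lonicera japonica	30	5	4	1	0	1	0	4	3	2	1	5	1	0	0	4	4	2	3	8	0	7	1	6	20	21
Plant	Dicotyledoneae	Lonicera japonica var. chinensis	27	5	4	1	0	1	0	4	3	2	1	3	1	0	0	3	4	2	3	8	0	5	1	6	17	21
Plant	Monocotyledoneae	Zea mays	51	15	6	1	0	0	8	0	10	6	5	14	0	0	0	0	9	7	17	7	1	8	1	35	28	45
Plant	Monocotyledoneae	Sorghum bicolor	36	6	6	1	0	0	5	0	2	4	2	5	0	1	0	0	2	3	6	6	1	2	1	14	13	44
Plant	Monocotyledoneae	Oryza sativa	57	4	5	2	0	0	8	0	2	3	2	5	0	13	0	0	3	6	11	9	1	1	1	21	18	53
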