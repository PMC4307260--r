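subgroup	count
I.1	593
I.2	89
I.3	107
I.4	14
I.5	45
I.6	12
I.7	21
I.8	40
I.9	49
I.10	47
I.11	35
I.12	62
I.13	2
I.14	24
II.1	1
II.2	7
II.3	54
II.4	54
II.5	94
II.6	85
II.7	9
II.8	55
II.9	14
II.10	197
II.11	201
III	443
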