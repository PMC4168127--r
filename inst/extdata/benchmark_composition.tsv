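dataset	ligand	split	n_seq	num_pos	num_neg	printed_ratio
ATP168	ATP	cv	168	3104	59226	19
NUC5	ATP	cv	227	3393	80409	24
NUC5	ADP	cv	321	4688	121158	26
NUC5	AMP	cv	140	1756	44009	25
NUC5	GTP	cv	56	875	21401	24
NUC5	GDP	cv	105	1577	36561	23
NUC5	ATP	independent	17	248	6974	28
NUC5	ADP	independent	26	405	10553	26
NUC5	AMP	independent	20	263	6057	23
NUC5	GTP	independent	7	134	2678	20
NUC5	GDP	independent	7	94	2420	26
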