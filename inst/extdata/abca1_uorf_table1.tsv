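# Published comparative table of the conserved uORF in ABCA1 orthologs:
# printed start/stop coordinates (from the TSS, 1-based), stop-inclusive
# length, peptide, and the annotated main-ORF start. Used as input for the
# coordinate-arithmetic regression suite.
species	group	uorf_start	uorf_stop	len_nt	len_aa	peptide	morf_start
Human	primates	307	417	111	36	MTSHGVPAVSSGRCLPGLPSHTLGVLAEGTWLVGLS	396
Macaque	primates	364	474	111	36	MTSHGIPAVSSGRCLPGLLSHTLWVLAEGTWLVGLS	453
Mouse lemur	primates	314	424	111	36	MTSHSIPAVSSGHCLPGLLSHTLWVPAEVTWLVGPS	403
Rabbit	other_placental	327	440	114	37	MTSHSGFATSSGRCLQGRATSRLPWVPAEVTWPAGLS	419
Mouse	rodents	224	319	96	31	MTSHRVTALCSGCSLQGSRAADAGRCGCRLW	321
Squirrel	rodents	279	365	87	28	MTSHSVCCELRPVPPGLLSHTQVALGAG	372
Cat	other_placental	304	393	90	29	MTSHSVPAVSCCCCLQKLLSHTQVAAAAG	400
Armadillo	other_placental	304	399	96	31	MTSHSVPAVSSGHCPHGLPTSHTQVAWARLR	401
Tasmanian devil	marsupials	4	66	63	20	MTSHSVPAQRYLCSLHYLPG	96
Opossum	marsupials	333	395	63	20	MTSHGVLAQCCLCSLHYLLD	425
Platypus	platypus	54	131	78	25	MTSHSVPAVCCCHCPCHTRGAVPAC	138
Chicken	reptiles_birds	135	200	66	21	MPSHNVLVVYCCCCTKGRRHC	207
Flycatcher	reptiles_birds	4	60	57	18	MPGHNICTVLLLLHKESF	77
Anole lizard	reptiles_birds	221	271	51	16	MTSHSSSAVCCFHPRC	295
Coelacanth	coelacanth	245	274	30	9	MSDNNIPAA	297
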