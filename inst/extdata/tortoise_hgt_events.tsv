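cog_class	function_label	donor_phylum	donor_kingdom	distribution	occurrence_in_reference	same_donor
[O] Posttranslational modification, protein turnover, chaperones	DsbA	Cnidaria	Metazoa	Both	Yes	No
[L] Replication, recombination and repair	methylated DNA protein-cysteine methyl transferase	Firmicutes	Bacteria	Both	Yes	Yes
[J] Translation, ribosomal structure and biogenesis	GTP-binding	Mixed phyla	Bacteria	Both	Yes	Yes
[E] Amino acid transport and metabolism	ADP-ribosyl arginine hydrolases	Firmicutes	Bacteria	T	Yes	Yes
[E] Amino acid transport and metabolism	Aspartate-ammonia ligase	Bacteroidetes	Bacteria	Both	Yes	Yes
[E] Amino acid transport and metabolism	Cysteine synthase	Firmicutes	Bacteria	Both	Yes	No
[E] Amino acid transport and metabolism	Tryptophan synthase (trpB)	Verrucomicrobia	Bacteria	T	Yes	Yes
[H] Coenzyme transport and metabolism	dephospho CoA kinase		Amoebozoa	T	Yes	Yes
[H] Coenzyme transport and metabolism	NadB (L-aspartate oxidase)	Myxococcota	Bacteria	Both	Yes	Yes
[C] Energy production and conversion	Lactate dehydrogenase and 2-hydroxyacid dehydrogenase	Firmicutes	Bacteria	Both	Yes	Yes
[C] Energy production and conversion	lipoamide dehydrogenase	Mixed phyla	Bacteria	Both	Yes	Yes
[C] Energy production and conversion	bifunctional aldehyde/alcohol DH family of Fe-ADH	Cyanobacteria	Bacteria	Both	Yes	Yes
[F] Nucleotide transport and metabolism	guanine deaminase	Firmicutes	Bacteria	B	No	N/A
[F] Nucleotide transport and metabolism	thymidine kinase	Alpha-Proteobacteria	Bacteria	T	Yes	Yes
[F] Nucleotide transport and metabolism	anaerobic ribonucleoside triphosphate reductase	TM6	Bacteria	Both	Yes	Yes
[Q] Secondary metabolites biosynthesis, transport and catabolism	Dehydrogenases	Firmicutes	Bacteria	Both	Yes	Yes
[Q] Secondary metabolites biosynthesis, transport and catabolism	Dehydrogenases	Firmicutes	Bacteria	T	Yes	Yes
[KO] Metabolism of terpenoids and polyketides	Squalene-hopene cyclase	Ciliophora	Alveolata	Both	Yes	Yes
[G] Carbohydrate transport and metabolism	GH13	Firmicutes	Bacteria	Both	Yes	Yes
[G] Carbohydrate transport and metabolism	GH1	Firmicutes	Bacteria	Both	Yes	Yes
[G] Carbohydrate transport and metabolism	GH5	Firmicutes	Bacteria	Both	Yes	Yes
[G] Carbohydrate transport and metabolism	GH43	Firmicutes	Bacteria	Both	Yes	Yes
[G] Carbohydrate transport and metabolism	GH10	Firmicutes	Bacteria	Both	Yes	Yes
[G] Carbohydrate transport and metabolism	GH11	Fibrobacteres	Bacteria	T	Yes	Yes
[G] Carbohydrate transport and metabolism	GH88	Mollicutes/Firmicutes	Bacteria	Both	Yes	Yes
[G] Carbohydrate transport and metabolism	GH3	Firmicutes	Bacteria	B	Yes	Yes
[G] Carbohydrate transport and metabolism	GH53	Firmicutes	Bacteria	Both	No	N/A
[G] Carbohydrate transport and metabolism	GH48	Firmicutes and Actinobacteria	Bacteria	T	Yes	Yes
[G] Carbohydrate transport and metabolism	CE1	Firmicutes and Fibrobacteres	Bacteria	B	Yes	Yes
[G] Carbohydrate transport and metabolism	CE15	Bacteroidetes	Bacteria	Both	Yes	Yes
[G] Carbohydrate transport and metabolism	PL4	Bacteroidetes	Bacteria	Both	Yes	Yes
[KO] Not Included in Pathway or Brite	aminopeptidase (Peptidase MEROPS Family M18)	Firmicutes	Bacteria	Both	No	N/A
No COG/KEGG	TerD_like	Firmicutes	Bacteria	Both	No	N/A
No COG/KEGG	uncharacterized protein		Metazoa	Both	No	N/A
No COG/KEGG	uncharacterized protein	Firmicutes	Bacteria	Both	No	N/A
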