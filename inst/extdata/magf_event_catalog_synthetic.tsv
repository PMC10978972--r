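function_label	donor_phylum	donor_kingdom
DsbA	Proteobacteria	Bacteria
methylated DNA protein-cysteine methyl transferase	Firmicutes	Bacteria
GTP-binding	Mixed phyla	Bacteria
ADP-ribosyl arginine hydrolases	Firmicutes	Bacteria
Aspartate-ammonia ligase	Bacteroidetes	Bacteria
Cysteine synthase	Actinobacteria	Bacteria
Tryptophan synthase (trpB)	Verrucomicrobia	Bacteria
dephospho CoA kinase		Amoebozoa
NadB (L-aspartate oxidase)	Myxococcota	Bacteria
Lactate dehydrogenase and 2-hydroxyacid dehydrogenase	Firmicutes	Bacteria
lipoamide dehydrogenase	Mixed phyla	Bacteria
bifunctional aldehyde/alcohol DH family of Fe-ADH	Cyanobacteria	Bacteria
thymidine kinase	Alpha-Proteobacteria	Bacteria
anaerobic ribonucleoside triphosphate reductase	TM6	Bacteria
Dehydrogenases	Firmicutes	Bacteria
Squalene-hopene cyclase	Ciliophora	Alveolata
GH13	Firmicutes	Bacteria
GH1	Firmicutes	Bacteria
GH5	Firmicutes	Bacteria
GH43	Firmicutes	Bacteria
GH10	Firmicutes	Bacteria
GH11	Fibrobacteres	Bacteria
GH88	Mollicutes/Firmicutes	Bacteria
GH3	Firmicutes	Bacteria
GH48	Firmicutes and Actinobacteria	Bacteria
CE1	Firmicutes and Fibrobacteres	Bacteria
CE15	Bacteroidetes	Bacteria
PL4	Bacteroidetes	Bacteria
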