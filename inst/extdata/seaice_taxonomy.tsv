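otu_id	domain	phylum	class	order	family	genus	confidence	type_strain	type_strain_score	organelle_flag
OTU_4	Bacteria	Proteobacteria	Gammaproteobacteria	Xanthomonadales	Xanthomonadaceae	Stenotrophomonas	NA	Stenotrophomonas maltophilia (T); ATCC 19867; AB021405	0.918	none
OTU_5	Bacteria	Actinobacteria	Actinobacteria	Corynebacteriales	Corynebacteriaceae	Corynebacterium	NA	Corynebacterium tuberculostearicum (T); CIP 107291; AJ438050	0.966	none
OTU_19	Bacteria	Proteobacteria	Gammaproteobacteria	Pseudomonadales	Pseudomonadaceae	Pseudomonas	NA	Pseudomonas proteolytica (T); CMS 64; AJ537603	0.954	none
OTU_22	Bacteria	Campylobacterota	Campylobacteria	Campylobacterales	Sulfurospirillaceae	Sulfurospirillum	NA	Sulfurospirillum alkalitolerans (T); HTRB-L1; GQ863490	0.742	none
OTU_25	Bacteria	Proteobacteria	Gammaproteobacteria	Pseudomonadales	Moraxellaceae	Acinetobacter	NA	Acinetobacter guillouiae (T); DSM 590; X81659	0.962	none
OTU_36	Bacteria	Proteobacteria	Alphaproteobacteria	Caulobacterales	Hyphomonadaceae	Asprobacter	NA	Asprobacter aquaticus (T); DRW22-8; KF056993	0.947	none
OTU_63	Bacteria	Proteobacteria	Gammaproteobacteria	Enterobacterales	Enterobacteriaceae	Escherichia/Shigella	NA	Shigella sonnei (T); CECT 4887; FR870445	0.977	none
OTU_70	Bacteria	Bacteroidota	Chitinophagia	Chitinophagales	Chitinophagaceae	NA	NA	Ferruginibacter alkalilentus (T); HU1-GD23; FJ177530	0.811	none
OTU_98	Bacteria	Proteobacteria	Betaproteobacteria	Burkholderiales	Burkholderiaceae	Burkholderia	NA	Burkholderia stabilis (T); LMG 14294; AF097533	0.954	none
OTU_103	Bacteria	Campylobacterota	Campylobacteria	Campylobacterales	Sulfurimonadaceae	Sulfurimonas	NA	Sulfurimonas denitrificans (T); DSM 1251; CP000153	0.865	none
OTU_167	Bacteria	Acidobacteriota	Blastocatellia	Blastocatellales	Blastocatellaceae	Aridibacter	NA	Aridibacter famidurans (T); A22_HD_4H; KF245634	0.918	none
OTU_209	Bacteria	Proteobacteria	Gammaproteobacteria	Pseudomonadales	Moraxellaceae	Acinetobacter	NA	Acinetobacter radioresistens (T); DSM 6976; X81666	1	none
OTU_1153	Bacteria	Campylobacterota	Campylobacteria	Campylobacterales	Sulfurospirillaceae	Sulfurospirillum	NA	Sulfurospirillum alkalitolerans (T); HTRB-L1; GQ863490	0.743	none
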