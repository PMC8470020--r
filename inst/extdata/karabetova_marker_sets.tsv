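bin_id	taxon	autotrophic_pathway	donor_ids	acceptor_ids	putative_metabolism	expected_labels
KA1	"Cloacimonadales"			hydA	Fermentation	fermentation
KA2	ANME-2a		mcrA;cooS		Anaerobic methane oxidation	anaerobic methane oxidation
KA3	Mariniphaga			coxA;hydA	Facultatively anaerobic	facultatively anaerobic
KA4	"Syntrophosphaera"			hydA	Fermentation	fermentation
KA5	Desulfocapsaceae	WL	cooS;hybC	napA;dsrA;dsrB	Autotrophic, nitrate reduction, sulfite reduction, H2 utilization	autotrophic;sulfite/sulfate reduction;nitrate reduction;H2 utilization
KA6	Desulfuromonadaceae		hybC	ccoN	H2 utilization	H2 utilization
KA7	Desulfobacterota	3-HP/4-HB	bzdN;bzdO;bzdP;bzdQ;hybC	coxA;ccoN;narG	Autotrophic, nitrate reduction, H2 and aromatic compound utilization	autotrophic;nitrate reduction;H2 utilization;aromatic compound utilization
KA8	Geopsychrobacteraceae		cooS;hybC	coxA;ccoN	Aerobic, H2 utilization	aerobic;H2 utilization
KA9	Phaeovulum		bglA;sqr;soeA	coxA;ccoN;nosZ	Aerobic, carbohydrates, sulfide and sulfite oxidation	sulfur compound oxidation;aerobic;carbohydrate utilization
KA10	Bacteroidales		hybC	hydA	Fermentation	fermentation
KA11	Sulfurimonas		soxY;soxZ;sqr	ccoN;napA	Sulfur compound oxidation, nitrate reduction	nitrate reduction;sulfur compound oxidation
KA12	Lentimicrobium			coxA;ccoN;hydA	Facultatively anaerobic	facultatively anaerobic
KA13	Bacteroidales			coxA;hydA	Facultatively anaerobic	facultatively anaerobic
KA14	Syntrophales	WL	cooS		Autotrophic	autotrophic
KA15	Burkholderiaceae		hybC	coxA;ccoN	Aerobic, H2 utilization	aerobic;H2 utilization
KA16	"Thiohalomonadaceae"	CBB	soxB;sqr;soeA	ccoN	Autotrophic, sulfur compounds oxidation	autotrophic;sulfur compound oxidation
KA17	Vicingaceae		bzdN;bzdO;bzdP;bzdQ	coxA;ccoN;narG;nosZ	Aerobic, denitrification, aromatic compound utilization	denitrification;aerobic;aromatic compound utilization
KA18	Coriobacteria		hybC		H2 utilization	H2 utilization
KA19	ANME-3		mcrA;cooS		Anaerobic methane oxidation	anaerobic methane oxidation
KA20	Anaerolineaceae		bglA;coxL;coxM;coxS;sqr;hyaB	coxA	Aerobic, organotrophic, sulfur compound oxidation, H2 utilization	sulfur compound oxidation;aerobic;H2 utilization;carbohydrate utilization
KA21	Bacteroidales			nosZ	Unidentified	Unidentified
KA22	Dethiobacteria	WL	cooS;cooF		Autotrophic, acetogenic	autotrophic;acetogenic
KA23	"Brevefilum"		bglA		Carbohydrates utilization	carbohydrate utilization
KA24	Archaea EX4484-52				Unidentified	Unidentified
KA25	Bacteroidales			coxA;hydA	Facultatively anaerobic	facultatively anaerobic
KA26	Trueperaceae	CBB	sqr;hybC	coxA	Autotrophic, sulfur compounds oxidation	autotrophic;sulfur compound oxidation
KA27	Archaea EX4484-52				Unidentified	Unidentified
KA28	"Marinisomatota"			hydA	Fermentation	fermentation
KA29	Methyloprofundus		pmoA;sqr	coxA	Aerobic methane and sulfide oxidation	aerobic methane oxidation;sulfur compound oxidation
KA30	"Patescibacteria"		bglA		Carbohydrate utilization	carbohydrate utilization
KA31	"Pacebacteria"		bglA		Carbohydrate utilization	carbohydrate utilization
KA32	"Pacearchaeales"				Unidentified	Unidentified
KA33	"Patescibacteria"				Unidentified	Unidentified
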