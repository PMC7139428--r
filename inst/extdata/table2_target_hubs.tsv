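gene	gene_name	mirna
Nr3c1	Nuclear receptor subfamily 3 group c member 1	rno-miR-141-3p
Nr3c1	Nuclear receptor subfamily 3 group c member 1	rno-miR-200a-3p
Nr3c1	Nuclear receptor subfamily 3 group c member 1	rno-miR-200c-3p
Jazf1	Juxtaposed with another zinc finger protein 1	rno-miR-141-3p
Jazf1	Juxtaposed with another zinc finger protein 1	rno-miR-200a-3p
Jazf1	Juxtaposed with another zinc finger protein 1	rno-miR-200c-3p
Rap2c	RAP2C, member of RAS oncogene family	rno-miR-141-3p
Rap2c	RAP2C, member of RAS oncogene family	rno-miR-200a-3p
Rap2c	RAP2C, member of RAS oncogene family	rno-miR-200c-3p
Zkscan1	Zinc finger with KRAB and SCAN domains 1	rno-miR-141-3p
Zkscan1	Zinc finger with KRAB and SCAN domains 1	rno-miR-200a-3p
Zkscan1	Zinc finger with KRAB and SCAN domains 1	rno-miR-293-5p
Pank3	Pantothenate kinase 3	rno-miR-141-3p
Pank3	Pantothenate kinase 3	rno-miR-200a-3p
Pank3	Pantothenate kinase 3	rno-miR-293-5p
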