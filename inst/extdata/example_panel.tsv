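name	formula	lmsd_category	mz	adducts	baseline	hotspot_log2fc	solvent_log2	log2fc_cerebrum	log2fc_cerebellum	log2fc_brain_stem	log2fc_midbrain	baseline_cerebrum	baseline_cerebellum	baseline_brain_stem	baseline_midbrain
psychosine	C24H47NO7	SP	NA	M+H=0.7;M+H-H2O=0.1;M+NH4=0.1;M+Na=0.1	6	2.5	-1	0	2.5	2.5	1	6	6	6	6
cholesterol	C27H46O	ST	NA	M+H-H2O=0.6;M+H=0.2;M+NH4=0.1;M+Na=0.1	1800	0	-1	0	0	0	0	1800	2400	2400	2000
GalCer(d18:1/18:0)	C42H81NO8	SP	NA	M+H=0.6;M+Na=0.4	400	0	-1	0.5	1.5	1.5	0.5	400	400	400	400
GalCer(d18:1/22:0)	C46H89NO8	SP	NA	M+H=1	300	0	-1	0.4	1.2	1.2	0.4	300	300	300	300
SM(d18:1/16:0)	C39H79N2O6P	SP	NA	M+H=0.7;M+Na=0.3	500	0	-1	0.8	0.8	0.8	0.8	500	500	500	500
oleic acid	C18H34O2	FA	NA	M+H=0.8;M+Na=0.2	300	0	-1	0	0	0	0	300	300	300	300
linoleic acid	C18H32O2	FA	NA	M+H=0.8;M+Na=0.2	250	0	-1	0	0	0	0	250	250	250	250
arachidonic acid	C20H32O2	FA	NA	M+H=0.8;M+Na=0.2	200	0	-1	0	0	0	0	200	200	200	200
EPA	C20H30O2	FA	NA	M+H=0.8;M+Na=0.2	150	0	-1	0	0	0	0	150	150	150	150
DHA	C22H32O2	FA	NA	M+H=0.8;M+Na=0.2	250	0	-1	0	0	0	0	250	250	250	250
PR01 305.2475	NA	PR	305.2475	M+H=1	300	0	-1	0	0	0	0	300	300	300	300
FA01 313.2737	NA	FA	313.2737	M+H=1	350	0	-1	0	0	0	0	350	350	350	350
FA01 315.2530	NA	FA	315.253	M+H=1	300	0	-1	0	0	0	0	300	300	300	300
FA07 548.5401	NA	FA	548.5401	M+H=1	400	0	-1	0	0	0	0	400	400	400	400
SP01 566.5506	NA	SP	566.5506	M+H=1	350	0	-1	0	0	0	0	350	350	350	350
GP01 758.5694	NA	GP	758.5694	M+H=1	500	0	-1	0	0	0	0	500	500	500	500
GP01 760.5851	NA	GP	760.5851	M+H=1	450	0	-1	0	0	0	0	450	450	450	450
SP01 761.5886	NA	SP	761.5886	M+H=1	300	0	-1	0	0	0	0	300	300	300	300
GP01/GP10 762.6007	NA	GP	762.6007	M+H=1	400	0	-1	0	0	0	0	400	400	400	400
GP01/GP10 764.5225	NA	GP	764.5225	M+H=1	350	0	-1	0	0	0	0	350	350	350	350
GP01/GP10 766.5381	NA	GP	766.5381	M+H=1	300	0	-1	0	0	0	0	300	300	300	300
GP01 768.5514	NA	GP	768.5514	M+H=1	300	0	-1	0	0	0	0	300	300	300	300
GP01 768.5538	NA	GP	768.5538	M+H=1	250	0	-1	0	0	0	0	250	250	250	250
GP01 772.5851	NA	GP	772.5851	M+H=1	350	0	-1	0	0	0	0	350	350	350	350
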