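genotype	laid	hatched
nos>Gal4/CyO; Mkrn1W/Mkrn1W	1222	40
FLAG-Mkrn1/nos>Gal4; Mkrn1W/Mkrn1W	2120	1690
Venus-Mkrn1/nos>Gal4; Mkrn1W/Mkrn1W	1180	895
nos>Gal4/CyO; Mkrn1S/Mkrn1S	12	0
FLAG-Mkrn1/nos>Gal4; Mkrn1S/Mkrn1S	750	465
Venus-Mkrn1/nos>Gal4; Mkrn1S/Mkrn1S	1320	1065
nos>Gal4/CyO; Mkrn1N/Mkrn1N	0	0
FLAG-Mkrn1/nos>Gal4; Mkrn1N/Mkrn1N	1030	760
Venus-Mkrn1/nos>Gal4; Mkrn1N/Mkrn1N	1255	1080
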