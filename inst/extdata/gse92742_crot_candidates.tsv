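ranking	pert_id	pert_iname	mean_expression	p_value
1	BRD-A28105619	cucurbitacin-i	-0.953	4.39E-14
2	BRD-A54927599	KF-38789	-0.883	5.68E-07
3	BRD-K74305673	IKK-2-inhibitor-V	-0.675	3.46E-08
4	BRD-K01976263	emetine	-0.666	4.16E-10
5	BRD-K35960502	niclosamide	-0.605	4.16E-14
6	BRD-K64642496	KO-143	-0.587	3.45E-07
7	BRD-K94325918	kinetin-riboside	-0.573	6.22E-08
8	BRD-K77987382	mebendazole	-0.568	1.31E-09
9	BRD-K26997899	D-64131	-0.544	2.06E-07
10	BRD-K83289131	CAY-10618	-0.528	1.56E-07
11	BRD-K05653692	DL-PDMP	-0.459	1.62E-08
12	BRD-K33272502	DG-041	-0.454	5.52E-07
13	BRD-A19633847	perhexiline	-0.453	4.42E-07
14	BRD-K74514084	pazopanib	-0.417	3.31E-07
15	BRD-K97764662	PD-173074	-0.370	1.78E-07
16	BRD-A84481105	thioridazine	-0.326	5.04E-10
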