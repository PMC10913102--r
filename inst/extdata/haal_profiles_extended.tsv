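sample_id	rank	name	parent	tsm	spepep	n_spectra_recorded
SS18	family	Rhodobacteraceae		5241	3820	10509
SS18	genus	Paracoccus	Rhodobacteraceae	5241	3820	10509
SS18	species	Paracoccus aeridis	Paracoccus	5114	2484	10509
HP23	family	Rhodobacteraceae		3111	1435	11333
HP23	genus	Roseovarius	Rhodobacteraceae	2795	596	11333
HP23	species	Roseovarius tolerans	Roseovarius	1711	34	11333
SS13	order	Chromatiales		3311	694	14637
SS13	order	Alteromonadales		2459	169	14637
SS13	family	Chromatiaceae	Chromatiales	3311	694	14637
SS13	family	Alteromonadaceae	Alteromonadales	2459	139	14637
SS13	genus	Rheinheimera	Chromatiaceae	3187	351	14637
SS13	genus	Arsukibacterium	Chromatiaceae	2269	49	14637
SS13	genus	Alishewanella	Alteromonadaceae	2181	108	14637
SS13	species	Rheinheimera pacifica	Rheinheimera	2095	39	14637
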