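sample_id	rank	name	parent	tsm	spepep	n_spectra_recorded	identity_best_hit	identity_pct
SS18	family	Rhodobacteraceae		5241	3820	10509	Paracoccus aeridis	99.47
SS18	genus	Paracoccus	Rhodobacteraceae	5241	3820	10509	Paracoccus aeridis	99.47
SS18	species	Paracoccus aeridis	Paracoccus	5114	2484	10509	Paracoccus aeridis	99.47
HP23	family	Rhodobacteraceae		3111	1435	11333	Roseovarius tibetensis	97.60
HP23	genus	Roseovarius	Rhodobacteraceae	2795	596	11333	Roseovarius tibetensis	97.60
HP23	species	Roseovarius tolerans	Roseovarius	1711	34	11333	Roseovarius tibetensis	97.60
HR17	family	Deinococcaceae		3269	2317	9721	Deinococcus yunweiensis	99.93
HR17	genus	Deinococcus	Deinococcaceae	3269	2317	9721	Deinococcus yunweiensis	99.93
HR17	species	Deinococcus metalli	Deinococcus	2243	138	9721	Deinococcus yunweiensis	99.93
SM24	family	unclassified Betaproteobacteria_family		3830	739	NA	Hydrogenophaga palleronii	98.57
SM24	genus	unclassified Betaproteobacteria_genus	unclassified Betaproteobacteria_family	3830	739	NA	Hydrogenophaga palleronii	98.57
SM24	species	Betaproteobacteria bacterium HGW-Betaproteobacteria-16	unclassified Betaproteobacteria_genus	3679	713	NA	Hydrogenophaga palleronii	98.57
SM33	family	Rhodobacteraceae		5114	1909	20713	Seohaeicola saemankumensis	98.71
SM33	genus	unclassified Rhodobacteraceae_genus	Rhodobacteraceae	3716	548	20713	Seohaeicola saemankumensis	98.71
SM33	species	Rhodobacteraceae bacterium EhC02	unclassified Rhodobacteraceae_genus	3716	548	20713	Seohaeicola saemankumensis	98.71
SS13	family	Chromatiaceae		3311	694	14637	Arsukibacterium ikkense	98.28
SS13	genus	Rheinheimera	Chromatiaceae	3187	351	14637	Arsukibacterium ikkense	98.28
SS13	species	Rheinheimera pacifica	Rheinheimera	2095	39	14637	Arsukibacterium ikkense	98.28
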