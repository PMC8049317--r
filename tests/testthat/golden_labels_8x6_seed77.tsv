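sample_id	protein_id	label
S001	P0001	observed
S001	P0002	mcar
S001	P0003	mnar_censored
S001	P0004	observed
S001	P0005	observed
S001	P0006	observed
S002	P0001	mnar_censored
S002	P0002	observed
S002	P0003	observed
S002	P0004	observed
S002	P0005	mcar
S002	P0006	observed
S003	P0001	mnar_censored
S003	P0002	observed
S003	P0003	observed
S003	P0004	mcar
S003	P0005	mcar
S003	P0006	observed
S004	P0001	mnar_censored
S004	P0002	observed
S004	P0003	observed
S004	P0004	mcar
S004	P0005	mcar
S004	P0006	observed
S005	P0001	mcar
S005	P0002	observed
S005	P0003	observed
S005	P0004	observed
S005	P0005	mnar_censored
S005	P0006	observed
S006	P0001	observed
S006	P0002	observed
S006	P0003	observed
S006	P0004	mcar
S006	P0005	observed
S006	P0006	observed
S007	P0001	observed
S007	P0002	observed
S007	P0003	mcar
S007	P0004	observed
S007	P0005	mcar
S007	P0006	observed
S008	P0001	mnar_censored
S008	P0002	observed
S008	P0003	observed
S008	P0004	mcar
S008	P0005	mnar_censored
S008	P0006	observed
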