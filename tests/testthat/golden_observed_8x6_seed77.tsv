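id	P0001	P0002	P0003	P0004	P0005	P0006
S001	15.049257925617461			15.88971813167732	17.230799894940006	18.842228284161006
S002		16.430005551040512	15.092047114699817	15.306325753221072		16.96661902051131
S003		16.5552474348329	15.659000028651541			17.266461309528225
S004		17.365771097860463	16.091820322927287			17.52333936645158
S005		15.014524228826321	14.287051210627416	14.289167657217257		14.062596118745461
S006	12.529422770664375	17.302407811305883	15.220730552283014		12.542229366746188	15.387406262577283
S007	13.132464643680365	15.079472197666375		16.909930977135339		16.705434135424156
S008		16.628444910324959	14.896704487563039			16.167206937713075
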