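name	d_third_percent	d_syn_percent	T_years	T_low	T_high	note
Nasonia	0.2	0.3	460000	NA	NA	host time averages bacterial and eukaryotic clock estimates
Drosophila	2.4	3.7	5500000	4650000	6350000	fossil-based host time; an alternative source gives 2.42 (1.16-3.37) MY, which does not reproduce the printed rate
Nomada	0.27666666666666667	0.44	2420000	1160000	3370000	divergences average the three ferruginata-vs-ingroup comparisons
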