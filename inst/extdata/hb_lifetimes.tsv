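# Mean continuous (tau_c), intermittent (tau_int) and monomer (tau_nb) lifetimes (fs)
# at the reference state points; err columns are 95% Student-t half-widths for the
# bond lifetimes and one standard deviation for tau_nb.
T_K	P_MPa	tau_c_fs	tau_c_err	tau_int_fs	tau_int_err	tau_nb_fs	tau_nb_err
293	0.1	320	2	5500	150	5.4	1.7
373	25	100.7	1.4	2269	111	10.0	2.7
473	25	65.7	1.1	937	17	13.9	2.3
573	10	48.7	2.4	486	16	21.4	2.1
623	22.5	43.3	1.7	364	23	31.8	3.8
653	25	42.5	1.8	323	15	61.3	6.9
673	25	44.1	4.9	305	13	244	21
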