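# Thermodynamic state points of the reference MD study of flexible 3-site water.
# Density was the NVE input; T_sim is the realised mean run temperature (sd in parentheses column).
T_K	rho_kg_L	P_MPa	T_sim_K	T_sim_sd_K
293	0.997	0.1	288.3	5.6
373	0.969	25	376.3	6.8
473	0.881	25	474.2	8.3
573	0.720	10	571.1	9.8
623	0.610	22.5	619.4	10.0
653	0.451	25	649.5	10.4
673	0.167	25	676.3	10.2
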