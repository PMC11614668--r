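block	parameter	value	unit
ra_neuron	g_na	1050	nS
ra_neuron	e_na	55	mV
ra_neuron	g_k	120	nS
ra_neuron	e_k	-90	mV
ra_neuron	g_l	3	nS
ra_neuron	e_l	-80	mV
ra_neuron	capacitance	10	pF
ra_neuron	m.v_half	-30	mV
ra_neuron	m.dv_eta	9.5	mV
ra_neuron	m.tau0	0.01	ms
ra_neuron	m.tau1	0	ms
ra_neuron	h.v_half	-45	mV
ra_neuron	h.dv_eta	-7	mV
ra_neuron	h.tau0	0.1	ms
ra_neuron	h.tau1	0.75	ms
ra_neuron	n.v_half	-35	mV
ra_neuron	n.dv_eta	10	mV
ra_neuron	n.tau0	0.1	ms
ra_neuron	n.tau1	0.5	ms
int_neuron	g_na	1200	nS
int_neuron	g_k	200	nS
int_neuron	g_l	3	nS
int_neuron	g_h	2	nS
int_neuron	e_h	-40	mV
int_neuron	g_cat	0.1	nS
int_neuron	ca_ext	2500	uM
int_neuron	ca0	1.11	uM
int_neuron	phi	3.88	uM/(ms.pA)
int_neuron	tau_ca	0.143	ms
int_neuron	H.v_half	-60	mV
int_neuron	H.dv_eta	-10	mV
int_neuron	H.dv_tau	-5.5	mV
int_neuron	H.tau0	214	ms
int_neuron	H.tau1	158	ms
int_neuron	a.v_half	-30	mV
int_neuron	a.dv_eta	32.9	mV
int_neuron	a.tau0	4.44	ms
int_neuron	a.tau1	4.24	ms
int_neuron	b.v_half	-62	mV
int_neuron	b.dv_eta	-62.5	mV
int_neuron	b.tau0	2.9	ms
int_neuron	b.tau1	7.57	ms
synapse	g_a11_int	8	nS
synapse	g_int_ra	8	nS
synapse	g_ra_int	7	nS
synapse	g_ra_ra_first	10	nS
synapse	g_ra_ra_chain	8.2	nS
synapse	e_gaba	-80	mV
synapse	e_ampa	0	mV
synapse	alpha_gaba	5	1/(mM.ms)
synapse	alpha_ampa	1.1	1/(mM.ms)
synapse	beta_gaba	0.18	1/ms
synapse	beta_ampa	0.19	1/ms
synapse	t_max	2.84	mM
synapse	k_p	5	mV
synapse	v_p	2	mV
trigger	t_min	0.001	mM
trigger	t_peak	2.84	mM
trigger	tau_r	1.2	ms
trigger	tau_f	1.2	ms
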