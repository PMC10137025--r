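approach	window_seconds	accuracy	precision	recall	specificity	f1
dfcp	12	0.9382	0.9381	0.9495	0.9264	0.9397
dfcp	24	0.9552	0.9420	0.9790	0.9314	0.9575
dfcp	36	0.9311	0.9204	0.9562	0.9076	0.9329
dfcp	48	0.9039	0.8877	0.9426	0.8650	0.9085
dfcp	60	0.8904	0.8827	0.9210	0.8595	0.8946
combined	12	0.9583	0.9520	0.9724	0.9450	0.9592
combined	24	0.9681	0.9541	0.9914	0.9450	0.9703
combined	36	0.9487	0.9281	0.9836	0.9129	0.9525
combined	48	0.9210	0.9006	0.9621	0.8802	0.9255
combined	60	0.9128	0.9017	0.9452	0.8821	0.9170
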