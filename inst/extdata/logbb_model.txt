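# Blood-brain barrier permeation (logBB) model: linear + truncated-power
# spline terms.  <a - x> denotes max(0, a - x) ("below" orientation);
# <x - a> is "above".  Evaluation: intercept + sum(linear) + sum(spline).
intercept	1.2827
linear	alogp98	0.17977
linear	dpsa1	-0.0033777
linear	num_h_acceptors	-0.18676
linear	s_sssN	0.1557
spline	s_ssCH2	4.6743	-0.022135	below
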