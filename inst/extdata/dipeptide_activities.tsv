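no	sequence	ranker_score	ahtpdb	biopep
1	I/LV	0.06~0.10	ACE inhibitor	stimulating
2	I/LI/L	0.22~0.62	ACE inhibitor	stimulating;dipeptidyl peptidase IV inhibitor
3	FI/L	0.95~0.99	ACE inhibitor
4	IF	0.95	ACE inhibitor	ACE inhibitor
5	DF	0.94	ACE inhibitor	ACE inhibitor
6	FQ	0.86	ACE inhibitor	ACE inhibitor;dipeptidyl peptidase IV inhibitor
7	VW	0.80	ACE inhibitor	ACE inhibitor;antioxidative;alpha-glucosidase inhibitor;dipeptidyl peptidase IV inhibitor
8	FF	1.00	ACE inhibitor	ACE inhibitor;dipeptidyl peptidase IV inhibitor
9	I/LW	0.94~0.99	ACE inhibitor	ACE inhibitor;dipeptidyl peptidase IV inhibitor
10	FR	0.99	ACE inhibitor	ACE inhibitor;dipeptidyl peptidase IV inhibitor
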