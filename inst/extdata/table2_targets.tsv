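label	full_name	location	network	protocol	n_patients	pct	outside_dlpfc
L46 (cTBS)	Left area 46	Brodmann area 46	Salience	cTBS	3	3.9	FALSE
L46 (iTBS)	Right area 46	Brodmann area 46	Salience	iTBS	1	1.3	FALSE
L8Av (cTBS)	Left area 8Av	Dorsolateral prefrontal cortex	CEN	cTBS	17	22.4	FALSE
L8Av (iTBS)	Left area 8Av	Dorsolateral prefrontal cortex	CEN	iTBS	2	2.6	FALSE
LPFm (cTBS)	Left area PFm complex	Inferior parietal cortex	CEN	cTBS	6	7.9	TRUE
LPGs (cTBS)	Left area PGs	Inferior parietal cortex	CEN	cTBS	13	17.1	TRUE
LPi (cTBS)	Para-insular area	Para-insular cortex	Salience	cTBS	1	1.3	TRUE
Ls6-8 (cTBS)	Left superior 6-8 transition area	Dorsolateral prefrontal cortex	CEN	cTBS	5	6.6	FALSE
LTe1m (cTBS)	Left area TE1 middle	Lateral temporal cortex	CEN	cTBS	7	9.2	TRUE
LTe1m (iTBS)	Left area TE1 middle	Lateral temporal cortex	CEN	iTBS	1	1.3	TRUE
R43 (cTBS)	Right area 43	Brodmann area 43	CEN	cTBS	2	2.6	TRUE
R46 (iTBS)	Right area 46	Brodmann area 46	Salience	iTBS	1	1.3	FALSE
R5mv (cTBS)	Right area 5 m ventral	Paracentral lobule	Salience	cTBS	1	1.3	TRUE
R8Av (cTBS)	Right area 8Av	Dorsolateral prefrontal cortex	CEN	cTBS	2	2.6	FALSE
RIFJp (iTBS)	Right area IFJp	Dorsolateral prefrontal cortex	CEN	iTBS	1	1.3	FALSE
Rp47r (iTBS)	Right area posterior 47r	Dorsolateral prefrontal cortex	CEN	iTBS	1	1.3	FALSE
RPFm (cTBS)	Right area PFm complex	Inferior parietal cortex	CEN	cTBS	1	1.3	TRUE
Rs6-8 (cTBS)	Right superior 6-8 transition area	Dorsolateral prefrontal cortex	CEN	cTBS	4	5.3	FALSE
RTe1m (cTBS)	Right area TE1 middle	Lateral temporal cortex	CEN	cTBS	7	9.2	TRUE
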