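happy	2.7	0.7	[3, 2, 3, 3, 2, 3, 3, 2, 3, 3]
joy	2.8	0.6	[3, 3, 2, 3, 3, 3, 2, 3, 3, 3]
love	3.2	0.5	[3, 3, 4, 3, 3, 3, 4, 3, 3, 3]
beautiful	2.9	0.6	[3, 3, 3, 2, 3, 3, 3, 3, 3, 2]
calm	1.3	0.8	[1, 2, 1, 1, 2, 1, 1, 2, 1, 1]
peaceful	2.2	0.7	[2, 2, 3, 2, 2, 2, 3, 2, 2, 2]
safe	1.8	0.8	[2, 2, 1, 2, 2, 2, 1, 2, 2, 2]
laugh	2.6	0.7	[3, 2, 3, 3, 2, 3, 3, 2, 3, 2]
warm	1.4	0.9	[1, 2, 1, 1, 2, 2, 1, 1, 2, 1]
free	1.9	0.8	[2, 2, 2, 1, 2, 2, 2, 2, 2, 2]
bright	1.6	0.8	[2, 1, 2, 2, 1, 2, 2, 1, 2, 1]
friend	2.1	0.7	[2, 2, 2, 3, 2, 2, 2, 2, 2, 2]
wonderful	3.0	0.5	[3, 3, 3, 3, 3, 3, 3, 3, 3, 3]
gentle	1.5	0.8	[2, 1, 2, 1, 2, 1, 2, 1, 2, 1]
excited	2.3	0.8	[2, 3, 2, 2, 3, 2, 2, 3, 2, 2]
terrified	-2.4	0.8	[-2, -3, -2, -2, -3, -2, -2, -3, -2, -3]
fear	-2.2	0.7	[-2, -2, -3, -2, -2, -2, -3, -2, -2, -2]
panic	-2.5	0.7	[-3, -2, -3, -2, -3, -2, -3, -2, -3, -2]
dark	-1.1	0.9	[-1, -1, -2, -1, -1, -1, -1, -1, -2, -1]
falling	-1.2	0.9	[-1, -2, -1, -1, -1, -2, -1, -1, -1, -1]
monster	-2.1	0.8	[-2, -2, -2, -3, -2, -2, -2, -2, -2, -2]
dead	-2.9	0.6	[-3, -3, -3, -2, -3, -3, -3, -3, -3, -2]
scream	-2.0	0.8	[-2, -2, -2, -2, -2, -2, -2, -2, -2, -2]
lost	-1.6	0.8	[-2, -1, -2, -2, -1, -2, -2, -1, -2, -1]
trapped	-2.3	0.7	[-2, -3, -2, -2, -3, -2, -2, -3, -2, -2]
angry	-2.2	0.7	[-2, -2, -2, -3, -2, -2, -2, -2, -3, -2]
sad	-2.1	0.7	[-2, -2, -2, -2, -2, -2, -3, -2, -2, -2]
alone	-1.3	0.9	[-1, -1, -2, -1, -1, -2, -1, -1, -1, -2]
danger	-2.4	0.7	[-2, -3, -2, -2, -2, -3, -2, -3, -2, -2]
cry	-1.9	0.8	[-2, -2, -2, -1, -2, -2, -2, -2, -2, -2]
storm	-1.0	0.9	[-1, -1, -1, -1, -1, -1, -1, -1, -1, -1]
chased	-1.8	0.8	[-2, -2, -1, -2, -2, -2, -1, -2, -2, -2]
anxious	-1.9	0.8	[-2, -2, -2, -2, -1, -2, -2, -2, -2, -2]
horror	-2.7	0.6	[-3, -3, -2, -3, -3, -2, -3, -3, -2, -3]
worried	-1.7	0.8	[-2, -2, -1, -2, -2, -1, -2, -2, -1, -2]
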