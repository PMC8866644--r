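patient	age	gender	stroke_type	lesion_side	lesion_location	months_since_stroke	dominant_hand	kbnt_pre1	kbnt_pre2	stimulation_site	fnirs_channel
1	49	male	infarction	left	middle cerebral artery territory	10	right	7/3/14	7/3/14	broca	5
2	67	female	infarction	left	middle cerebral artery territory	72	right	0/1/6	0/0/6	adjacent	8
3	45	male	infarction	left	basal ganglia	23	right	57/2/1	59/0/1	wernicke	10
4	60	male	infarction	left	middle cerebral artery territory	24	right	0/0/8	0/0/8	wernicke	10
5	60	female	hemorrhage	left	basal ganglia	73	right	25/3/17	25/3/17	wernicke	11
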