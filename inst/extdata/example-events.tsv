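patient_id	event_id	appearance_index	semantic_type	text	raw_time	causal_links
p1	e1	1	Sx	seizure	three days ago	e2
p1	e2	2	Test	EEG	three days ago
p1	e3	3	Drug	lorazepam	02.8.15
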