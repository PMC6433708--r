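name	doc_freq
Transcranial magnetic stimulation	495
Electrical stimulation	296
Induced movement therapy	251
Robot therapy	125
Mental practice	97
Mirror therapy	97
Intensive occupational therapy	95
Motor training	74
Somatosensory stimulation	60
Repetitive practice	48
Intensive training	44
Neuromuscular electrical stimulation	40
Bilateral training	32
Bilateral arm training	29
Noninvasive brain stimulation	27
Cortical stimulation	24
Tactile stimulation	24
Upper extremity training	24
Hand training	23
Neuromuscular stimulation	22
Median nerve stimulation	20
Task practice therapy	19
Aerobic exercise training	17
Unilateral training	17
Treadmill training	15
Peripheral nerve stimulation	14
Bimanual training	13
Gait training	13
Motor imagery training	13
Computer interface training	12
Smart arm training	12
Massed practice	10
Transcutaneous electrical nerve stimulation	10
Virtual reality training	10
Physical and occupational therapy	9
Active neuromuscular stimulation	8
Deep brain stimulation	7
Functional strength training	7
Functional task practice	7
Motor cortex stimulation	7
Music therapy	7
Wrist training	7
Based mental practice training	6
Constraint-induced movement therapy	6
Forced use therapy	6
Paired associative stimulation	6
Surface neuromuscular electrical stimulation	6
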