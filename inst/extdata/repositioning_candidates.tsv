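name	doc_freq
Cognitive behavior therapy	146
Massage therapy	30
Homeopathic treatment	16
Acupuncture treatments	12
Hand arm bimanual intensive training	7
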