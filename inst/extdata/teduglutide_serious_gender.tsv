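category	serious_n	nonserious_n
female	3266	2449
male	2130	1329
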