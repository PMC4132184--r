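# toy 10-edge interactome used in examples and tests
p01	p02	known
p01	p03	known
p02	p03	predicted
p03	p04	known
p04	p05	predicted
p05	p06	known
p02	p06	predicted
p06	p07	known
p07	p08	predicted
p01	p08	known
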