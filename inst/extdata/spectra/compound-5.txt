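# ESI(+)-MS2 peak list, nicotinamide (compound 5)
123 15
106 5
80 100
78 50
53 25
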