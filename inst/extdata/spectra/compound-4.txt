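# ESI(+)-MS2 peak list, 2-cyano-2-phenylbutanoic acid ethyl ester (compound 4)
218 47
190 100
162 10
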