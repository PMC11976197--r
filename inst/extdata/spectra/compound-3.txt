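# ESI(+)-MS2 peak list, delta-9,11-dehydro-17alpha-cyanomethylestradiol (compound 3)
310 100
292 92
275 8
269 12
265 72
251 10
159 35
157 14
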