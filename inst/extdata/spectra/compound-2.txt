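# ESI(+)-MS2 peak list, estriol 3-methyl ether (compound 2); m/z rel.int(%)
303 100
285 38
274 8
267 70
257 10
241 16
227 13
211 12
199 10
185 26
173 6
171 11
151 12
147 19
135 14
121 25
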