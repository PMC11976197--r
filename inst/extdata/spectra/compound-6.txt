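# ESI(+)-MS2 m/z list, quercetin (compound 6); intensities are uniform
# placeholders (only m/z values are documented), excluded from weighted scores
303 100
257 100
229 100
201 100
165 100
153 100
137 100
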