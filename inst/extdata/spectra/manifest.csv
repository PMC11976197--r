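# Manifest of packaged ESI(+)-MS2 peak lists (one two-column text file each).
# threshold: relative-intensity cutoff (%) used in the evaluation of this
# compound; range_lo/range_hi: acquisition mass range (Th).
label,file,ms_stage,threshold,range_lo,range_hi
2,compound-2.txt,2,5,100,320
3,compound-3.txt,2,5,150,320
4,compound-4.txt,2,10,60,220
5,compound-5.txt,2,5,50,130
6,compound-6.txt,2,10,100,320
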