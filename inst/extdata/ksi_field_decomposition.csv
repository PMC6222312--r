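group,WT,D103N,Y16S,D103L
RES 16,-47,-46,-2,-45
RES 103,-52,-36,-51,-4
RES 40,-26,-29,-22,-23
Sum of 3RS,-125,-111,-75,-72
Sum of ARS,-124,-93,-74,-66
Solvent,7,10,8,9
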