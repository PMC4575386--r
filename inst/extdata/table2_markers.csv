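label,mass,copper_sulfate_direction,copper_sulfate_mark,acridine_direction,acridine_mark,bnf_direction,bnf_mark
A,4562,none,none,down,**,up,*
B,4576,none,none,none,none,up,*
C,4633,up,**,down,**,up,*
D,4647,none,none,down,*,up,*
E,4885,none,none,none,none,down,**
F,4902,none,none,up,**,down,**
G,5655,up,*,none,none,none,none
H,6275,none,none,none,none,up,*
I,6731,up,**,none,none,none,none
J,10540,up,*,none,none,none,none
K,11295,up,**,up,*,down,*
L,13448,up,**,up,*,down,*
M,13627,none,none,up,*,none,none
N,13705,up,*,none,none,none,none
O,15292,up,*,none,none,none,none
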