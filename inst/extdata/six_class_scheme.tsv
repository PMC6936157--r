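# six-class physicochemical reduction of the 20 standard amino acids
# format: <class_symbol><TAB><comma-separated residues>
L	R,D,E,N,Q,K,H
B	L,I,V,A,M,F
W	S,T,Y,W
P	P
G	G
C	C
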