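MEME version 4

ALPHABET= ACGT

strands: + -

Background letter frequencies
A 0.25 C 0.25 G 0.25 T 0.25

MOTIF CREB_like_synthetic
letter-probability matrix: alength= 4 w= 10 nsites= 20 E= 0
 0.04 0.04 0.04 0.88
 0.04 0.04 0.88 0.04
 0.88 0.04 0.04 0.04
 0.04 0.88 0.04 0.04
 0.04 0.04 0.88 0.04
 0.04 0.04 0.04 0.88
 0.04 0.88 0.04 0.04
 0.88 0.04 0.04 0.04
 0.04 0.04 0.04 0.88
 0.04 0.04 0.04 0.88

MOTIF GATA_like_synthetic
letter-probability matrix: alength= 4 w= 8 nsites= 20 E= 0
 0.88 0.04 0.04 0.04
 0.04 0.04 0.88 0.04
 0.88 0.04 0.04 0.04
 0.04 0.04 0.04 0.88
 0.88 0.04 0.04 0.04
 0.88 0.04 0.04 0.04
 0.04 0.04 0.88 0.04
 0.88 0.04 0.04 0.04

MOTIF ETS_like_synthetic
letter-probability matrix: alength= 4 w= 10 nsites= 20 E= 0
 0.88 0.04 0.04 0.04
 0.04 0.88 0.04 0.04
 0.04 0.88 0.04 0.04
 0.04 0.04 0.88 0.04
 0.04 0.04 0.88 0.04
 0.88 0.04 0.04 0.04
 0.88 0.04 0.04 0.04
 0.04 0.04 0.88 0.04
 0.04 0.04 0.04 0.88
 0.04 0.04 0.88 0.04

MOTIF GC_rich_synthetic
letter-probability matrix: alength= 4 w= 8 nsites= 20 E= 0
 0.04 0.04 0.88 0.04
 0.04 0.88 0.04 0.04
 0.04 0.04 0.88 0.04
 0.04 0.04 0.88 0.04
 0.04 0.88 0.04 0.04
 0.04 0.04 0.88 0.04
 0.04 0.04 0.88 0.04
 0.04 0.88 0.04 0.04

MOTIF AT_rich_synthetic
letter-probability matrix: alength= 4 w= 8 nsites= 20 E= 0
 0.88 0.04 0.04 0.04
 0.04 0.04 0.04 0.88
 0.04 0.04 0.04 0.88
 0.88 0.04 0.04 0.04
 0.04 0.04 0.04 0.88
 0.88 0.04 0.04 0.04
 0.88 0.04 0.04 0.04
 0.04 0.04 0.04 0.88

MOTIF HOX_like_synthetic
letter-probability matrix: alength= 4 w= 8 nsites= 20 E= 0
 0.04 0.04 0.04 0.88
 0.04 0.04 0.04 0.88
 0.88 0.04 0.04 0.04
 0.88 0.04 0.04 0.04
 0.04 0.04 0.04 0.88
 0.04 0.04 0.04 0.88
 0.88 0.04 0.04 0.04
 0.88 0.04 0.04 0.04
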