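# Morphological data matrix: six Bicorniphontodes species and the outgroup
# Laophontodes typicus; 41 characters (numbered 0-40), states 0-2, ? unknown.
Laophontodes_typicus           1000000001 0000000010 1111110010 1101100110 2
Bicorniphontodes_bicornis      1111100100 0000000100 10010??000 1111000011 2
Bicorniphontodes_clarae        1111110201 0100000100 0110011111 1011100011 2
Bicorniphontodes_horstgeorgei  0011101111 0010100110 0000111100 1111100012 2
Bicorniphontodes_lacuna        0011112201 0111100110 0000000100 0110110000 0
Bicorniphontodes_comptus       0111101201 0110110111 0000000100 0110100000 1
Bicorniphontodes_huysi         0011101001 1110101100 0000000100 0110101000 1
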