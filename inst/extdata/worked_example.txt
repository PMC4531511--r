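# Three-reaction interaction network with one quantitatively regulated
# reaction: A_ppi_B carries a positive (K+ B--C) and a negative (K- A--D)
# quantitative modifier; B_ppi_C and A_ppi_D are contingency-free.
B_ppi_C
A_ppi_D
A_ppi_B; K+ B--C; K- A--D
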