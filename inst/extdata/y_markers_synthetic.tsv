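haplogroup	marker_id	ancestral	derived
O2	O2_1	T	C
O2	O2_2	A	G
O2	O2_3	T	A
O2a	O2a_1	G	C
O2a	O2a_2	C	G
O2a	O2a_3	C	A
O2a1	O2a1_1	T	A
O2a1	O2a1_2	T	C
O2a1	O2a1_3	G	C
O2a2	O2a2_1	C	G
O2a2	O2a2_2	T	C
O2a2	O2a2_3	A	C
O1b	O1b_1	G	C
O1b	O1b_2	C	G
O1b	O1b_3	G	A
C2	C2_1	T	C
C2	C2_2	G	A
C2	C2_3	C	G
C2b	C2b_1	T	G
C2b	C2b_2	T	A
C2b	C2b_3	C	G
C2c	C2c_1	T	G
C2c	C2c_2	G	C
C2c	C2c_3	C	T
N1a	N1a_1	G	A
N1a	N1a_2	T	G
N1a	N1a_3	T	G
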