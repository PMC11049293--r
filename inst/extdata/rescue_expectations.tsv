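protein_id	tw_vs_ew	tf_vs_tw
EXOC8	down	up
AP2A1	down	up
AP2A2	down	up
AP2B1	down	up
DMXL2	down	up
CLTA	down	up
CLTB	down	up
CLTC	down	up
SCYL2	down	up
EXOC1	down	up
EXOC3	down	up
HIP1	down	up
ITSN1	down	up
NRXN1	down	up
YWHAG	down	up
SACM1L	down	up
SNAP91	down	up
UBE3A	up	down
FMR1	up	down
MYO5A	up	down
DBN1	up	down
GRIN2A	up	down
MYO1D	up	down
SPTBN2	up	down
RAB5B	up	down
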