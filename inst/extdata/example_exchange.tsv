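#dataset_id	example
#growth_rate	0.0073138727510880606
#growth_sd	0
#productivity	0
#productivity_sd	0
#dry_mass	264
metabolite	value	sd	is_aa
glc__D	-0.142179983537644	0	FALSE
lac__L	0	0	FALSE
gln__L	-0.0600207325164229	0	TRUE
ala__L	-0.02	0	TRUE
ser__L	-0.02	0	TRUE
gly	-0.02	0	TRUE
his__L	-0.012553041864885	0	TRUE
lys__L	-0.0181404790836386	0	TRUE
thr__L	-0.0156468977662735	0	TRUE
trp__L	-0.00390969845093787	0	TRUE
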