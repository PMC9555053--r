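# Nearest-neighbour RNA/RNA stack free energies, kcal/mol at 37 C.
# Watson-Crick stacks after Xia et al. (1998); top strand 5'->3', bottom
# strand 3'->5'. Stacks involving G.U wobble pairs are handled by the flat
# gu_stack parameter of nn_params() (simplified model), not listed here.
top	bottom	dg
AA	UU	-0.93
UU	AA	-0.93
AU	UA	-1.10
UA	AU	-1.33
CU	GA	-2.08
AG	UC	-2.08
CA	GU	-2.11
UG	AC	-2.11
GU	CA	-2.24
AC	UG	-2.24
GA	CU	-2.35
UC	AG	-2.35
CG	GC	-2.36
GG	CC	-3.26
CC	GG	-3.26
GC	CG	-3.42
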