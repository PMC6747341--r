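# Minimal nonbonded parameter table: resname, atom name, partial charge (e),
# LJ sigma (nm), LJ epsilon (kJ/mol). Divalent cation LJ parameters follow the
# CM non-bonded model of Li et al.; protein heavy-atom values are generic
# CHARMM-like per-atom-class approximations; resname * is a per-name fallback.
resname	name	charge	sigma	epsilon
ZN	ZN	2.000	0.226466454151	0.01381916624
CA	CA	2.000	0.293818397243	0.44320568080
NA	NA	1.000	0.243	0.196
CL	CL	-1.000	0.404	0.628
SOL	OW	-0.834	0.315	0.636
SOL	HW1	0.417	0.040	0.192
SOL	HW2	0.417	0.040	0.192
*	N	-0.470	0.329	0.836
*	CA	0.070	0.356	0.120
*	C	0.510	0.356	0.460
*	O	-0.510	0.302	0.502
*	CB	-0.180	0.365	0.330
*	CG	-0.180	0.365	0.330
*	CD	-0.180	0.365	0.330
*	OD1	-0.760	0.302	0.502
*	OD2	-0.760	0.302	0.502
*	OE1	-0.760	0.302	0.502
*	OE2	-0.760	0.302	0.502
*	ND1	-0.360	0.329	0.836
*	NE2	-0.360	0.329	0.836
*	OG	-0.650	0.307	0.711
*	OH	-0.540	0.307	0.711
*	SD	-0.090	0.356	1.046
*	SG	-0.230	0.356	1.046
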