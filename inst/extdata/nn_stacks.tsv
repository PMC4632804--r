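param	dH_kcal_mol	dS_cal_molK
AA	-7.9	-22.2
AT	-7.2	-20.4
AG	-7.8	-21.0
AC	-8.4	-22.4
TA	-7.2	-21.3
TT	-7.9	-22.2
TG	-8.5	-22.7
TC	-8.2	-22.2
CA	-8.5	-22.7
CT	-7.8	-21.0
CG	-10.6	-27.2
CC	-8.0	-19.9
GA	-8.2	-22.2
GT	-8.4	-22.4
GG	-8.0	-19.9
GC	-9.8	-24.4
init_AT	2.3	4.1
init_GC	0.1	-2.8
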