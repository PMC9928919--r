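Alignment ID	Average Mz	Average Rt(min)	S/N	MS1 isotopic ratio	Sample_1	Sample_2	Sample_3	Sample_4	Sample_5	Sample_6	Sample_7
141	83.0501	5.82		0.060	165,052	119,320	114,649	66,851	149,155	108,584	56,291
142	83.0502	5.70		0.058	165,052	119,320	114,649	66,851	149,155	108,584	56,291
185	89.06	6.07		0.046	903,124	0	723,861	77,930	0	0	69,978
187	89.0601	5.85		0.050	560	541,018	723,861	5,686	41,555	437,522	530
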