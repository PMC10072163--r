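chr7	0	5000000	p22.3	gneg
chr7	5000000	25000000	p21.1	gneg
chr7	25000000	45000000	p14.1	gneg
chr7	45000000	60000000	p11.2	gneg
chr7	60000000	66000000	q11.21	gneg
chr7	66000000	72000000	q11.22	gneg
chr7	72000000	78000000	q11.23	gneg
chr7	78000000	85000000	q21.11	gneg
chr7	85000000	91000000	q21.12	gneg
chr7	91000000	98000000	q21.3	gneg
chr7	98000000	104000000	q22.1	gneg
chr7	104000000	111000000	q31.1	gneg
chr7	111000000	118000000	q31.2	gneg
chr7	118000000	124000000	q31.31	gneg
chr7	124000000	131000000	q31.33	gneg
chr7	131000000	138000000	q32.1	gneg
chr7	138000000	145000000	q33	gneg
chr7	145000000	152000000	q34	gneg
chr7	152000000	160000000	q36.1	gneg
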