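# Synthetic example limiting-dilution table (columns: pg input per well,
# positive wells, total wells). Eight replicate wells per dilution.
input_pg	wells_positive	wells_total
1	1	8
3	2	8
10	5	8
30	8	8
100	8	8
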