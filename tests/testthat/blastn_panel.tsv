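query_id	subject_id	percent_identity	alignment_length
q01	s01	73.08	1289
q02	s02	90.569	615
q03	s03	84.651	1075
q04	s04	79.743	1091
q05	s05	84.068	703
q06	s06	85.344	655
q07	s07	91.734	871
q08	s08	89.589	1191
q09	s09	80.153	1043
q10	s10	81.963	754
q11	s11	83.258	884
q12	s12	92.22	874
q13	s13	72.879	719
q14	s14	82.538	1466
q15	s15	78.862	1178
q16	s16	83.353	865
q17	s17	79.017	977
q18	s18	74.623	1060
q19	s19	79.947	753
q20	s20	77.885	1456
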