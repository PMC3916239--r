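# motif=HELPER cutoff=5.5099999999999998
pos	A	C	G	T
1	-3.3219280948873622	-3.3219280948873622	1.8875252707415875	-3.3219280948873622
2	-3.3219280948873622	1.8875252707415875	-3.3219280948873622	-3.3219280948873622
3	-3.3219280948873622	1.8875252707415875	-3.3219280948873622	-3.3219280948873622
4	0.37851162325372983	-3.3219280948873622	1.3219280948873624	-3.3219280948873622
5	1.722466024471091	-1	-3.3219280948873622	-3.3219280948873622
6	-0.15200309344504995	0.37851162325372983	-0.15200309344504995	-0.15200309344504995
7	1.0703893278913981	-3.3219280948873622	-3.3219280948873622	0.76553474636297703
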