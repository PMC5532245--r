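# Default aggregation of the 44 CORINE land-cover codes to the 14 SEEA classes
corine_code,seea_code
111,1
112,1
121,1
122,1
123,1
124,1
131,1
132,1
133,1
141,1
142,1
211,2
212,2
213,2
221,3
222,3
223,3
241,4
242,4
243,4
244,4
231,5
321,5
311,6
312,6
313,6
324,6
322,8
323,8
411,9
412,9
333,10
331,11
332,11
334,11
335,12
511,13
512,13
421,14
422,14
423,14
521,14
522,14
523,14
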