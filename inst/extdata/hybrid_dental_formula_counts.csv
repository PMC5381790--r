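site,lineage,formula,count
AS;NO,B-01,"1,5–5,1",45
AS;NO,B-01,"1,5–4,1",48
AS-13,B-02,"1,5–5,1",6
AS-13,B-02,"1,5–4,1",4
RI-2,A-11,"1,5–5,1",2
RI-2,A-11,"1,5–4,1",4
RI-2,B-03,"1,5–5,1",3
SF-4,B-06,"1,5–5,1",6
SF-12,A-18,"1,5–5,1",3
SF-12,A-18,"1,5–4,1",1
SF-13,A-06,"1,5–5,1",18
SF-13,A-06,"2,5–5,1",1
SF-13,A-07,"1,5–5,1",5
SF-13,A-07,"0,5–5,0",6
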