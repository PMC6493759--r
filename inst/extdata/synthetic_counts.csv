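site,sp1,sp2,sp3,sp4
site01,0,3,1,3
site02,1,1,0,0
site03,2,6,1,16
site04,0,1,0,4
site05,0,0,0,2
site06,2,1,1,6
site07,0,0,1,2
site08,0,4,2,0
site09,0,2,0,1
site10,1,1,0,2
site11,2,3,0,1
site12,0,5,0,5
site13,0,1,1,7
site14,0,1,1,3
site15,0,0,0,1
site16,0,1,0,7
site17,1,1,0,3
site18,0,2,0,0
site19,0,2,1,5
site20,0,2,3,0
site21,0,2,1,0
site22,2,1,1,2
site23,1,2,3,1
site24,1,1,2,0
site25,0,2,0,3
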