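site,x1
site01,-0.560475646552213
site02,-0.23017748948328
site03,1.55870831414912
site04,0.070508391424576
site05,0.129287735160946
site06,1.71506498688328
site07,0.460916205989202
site08,-1.26506123460653
site09,-0.686852851893526
site10,-0.445661970099958
site11,1.22408179743946
site12,0.359813827057364
site13,0.400771450594052
site14,0.11068271594512
site15,-0.555841134754075
site16,1.78691313680308
site17,0.497850478229239
site18,-1.96661715662964
site19,0.701355901563686
site20,-0.472791407727934
site21,-1.06782370598685
site22,-0.217974914658295
site23,-1.02600444830724
site24,-0.72889122929114
site25,-0.625039267849257
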