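class,adenoma,carcinoma,normal
adenoma,4,1,0
carcinoma,3,5,0
normal,0,0,16
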