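island,pre_european,current_total,current_native,exotic
San Felix,9,15,9,6
San Ambrosio,19,25,19,6
Easter,40,366,26,340
Robinson Crusoe,100,575,98,477
Santa Clara,12,53,12,41
Alejandro Selkirk,71,217,69,148
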