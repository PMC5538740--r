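island,lat,lon
San Felix,-26.2833,-80.0833
San Ambrosio,-26.3333,-79.8833
Easter,-27.1,-109.3333
Robinson Crusoe,-33.6333,-78.8333
Santa Clara,-33.7,-78.9333
Alejandro Selkirk,-33.75,-80.7833
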