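island,period,scope,pd,mpd,mntd
San Felix,pre_european,complete,889,227.9,156.7
San Felix,current,complete,1031,213.5,88.1
San Felix,current,native_only,709,249.4,190.1
San Felix,current,exotic_only,661,199.5,80.3
San Ambrosio,pre_european,complete,1472,240.3,94.3
San Ambrosio,current,complete,1607,225.5,76.8
San Ambrosio,current,native_only,1151,240.9,135.5
San Ambrosio,current,exotic_only,1003,210.5,108.1
Easter,pre_european,complete,2849,261.2,111.9
Easter,current,complete,12760,257.6,46.8
Easter,current,native_only,885,216.4,67.9
Easter,current,exotic_only,12580,257.0,47.9
Robinson Crusoe,pre_european,complete,4701,259.4,57.7
Robinson Crusoe,current,complete,18078,260.6,41.6
Robinson Crusoe,current,native_only,4247,259.5,61.0
Robinson Crusoe,current,exotic_only,16081,260.2,42.8
Santa Clara,pre_european,complete,1083,231.2,132.3
Santa Clara,current,complete,2802,236.0,69.3
Santa Clara,current,native_only,935,231.9,131.6
Santa Clara,current,exotic_only,5432,238.3,73.6
Alejandro Selkirk,pre_european,complete,3725,265.4,60.6
Alejandro Selkirk,current,complete,7646,255.7,43.6
Alejandro Selkirk,current,native_only,3195,267.4,71.4
Alejandro Selkirk,current,exotic_only,5977,250.3,46.7
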