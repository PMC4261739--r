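label,piece,phi,psi
core-alpha,1,-160,-90
core-alpha,1,-20,-90
core-alpha,1,-20,45
core-alpha,1,-160,45
core-beta,1,-180,90
core-beta,1,-45,90
core-beta,1,-45,180
core-beta,1,-180,180
core-beta,2,-180,-180
core-beta,2,-45,-180
core-beta,2,-45,-150
core-beta,2,-180,-150
core-L,1,20,-20
core-L,1,100,-20
core-L,1,100,90
core-L,1,20,90
allowed,1,-180,-120
allowed,1,0,-120
allowed,1,0,60
allowed,1,-180,60
allowed,2,-180,60
allowed,2,-20,60
allowed,2,-20,180
allowed,2,-180,180
allowed,3,-180,-180
allowed,3,-20,-180
allowed,3,-20,-140
allowed,3,-180,-140
allowed,4,0,-60
allowed,4,130,-60
allowed,4,130,110
allowed,4,0,110
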