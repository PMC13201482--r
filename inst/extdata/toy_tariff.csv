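dimension,level,decrement
intercept,,1.0
mo,1,0
mo,2,0.05
mo,3,0.10
mo,4,0.15
mo,5,0.20
sc,1,0
sc,2,0.04
sc,3,0.08
sc,4,0.12
sc,5,0.16
ua,1,0
ua,2,0.04
ua,3,0.08
ua,4,0.12
ua,5,0.16
pd,1,0
pd,2,0.06
pd,3,0.12
pd,4,0.18
pd,5,0.24
ad,1,0
ad,2,0.05
ad,3,0.10
ad,4,0.15
ad,5,0.20
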