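iso3,group
AAA,Region Alpha
BBB,Region Alpha
C01,Region Alpha
C02,Region Beta
C03,Region Beta
AAA,Continent North
BBB,Continent North
C01,Continent South
C02,Continent South
C03,Continent South
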