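pair5,pair3,dg
AU,AU,-0.9
AU,UA,-1.1
UA,AU,-1.3
AU,GC,-2.1
AU,CG,-2.2
UA,GC,-2.1
UA,CG,-2.4
GC,GC,-3.3
GC,CG,-3.4
CG,GC,-2.4
AU,GU,-0.6
AU,UG,-1.4
UA,GU,-1.0
UA,UG,-1.3
GC,GU,-1.5
GC,UG,-2.5
CG,GU,-1.4
CG,UG,-2.1
GU,GU,0.5
GU,UG,-0.5
UG,GU,0.4
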