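group,n,lsc_mm
automatic,1,1.6
automatic,3,0.9
mitral_surgery,1,2.4
mitral_surgery,2,1.7
mitral_surgery,3,1.4
manual,1,0.9
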