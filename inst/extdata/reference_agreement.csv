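analysis,bias_mm,loa_low_mm,loa_high_mm
overall,-1.4,-4.0,1.2
anterior,-1.4,-5.2,2.5
inferior,-0.9,-4.5,2.8
anterolateral,-3.0,-8.1,2.1
inferoseptal,-1.0,-5.2,3.2
anteroseptal,-0.7,-4.0,2.5
inferolateral,-0.7,-5.9,4.5
excluding_anterolateral,-1.1,-3.6,1.4
mitral_surgery,-0.6,-3.4,2.2
interobserver_manual,0.3,-1.2,1.9
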