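locus,allele,freq
L01,1,0.227375379802603
L01,2,0.137800571813675
L01,3,0.0995250183788697
L01,4,0.169903730592355
L01,5,0.365395299412498
L02,1,0.154377022913828
L02,2,0.167375445816895
L02,3,0.182532855397741
L02,4,0.214702215330436
L02,5,0.281012460541099
L03,1,0.190460967006872
L03,2,0.123032819660182
L03,3,0.286327363281825
L03,4,0.165451239369062
L03,5,0.234727610682058
L04,1,0.352918248260345
L04,2,0.278391377247348
L04,3,0.0425019620266174
L04,4,0.0956288796384978
L04,5,0.230559532827192
L05,1,0.177139538552883
L05,2,0.417441241498188
L05,3,0.0124843482571231
L05,4,0.147827886723182
L05,5,0.245106984968624
L06,1,0.197056515946302
L06,2,0.10765317460395
L06,3,0.184292158450211
L06,4,0.179120084727304
L06,5,0.331878066272233
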