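phantom,source_region,target_region,S_mGy_per_MBq_h
M,red_marrow,red_marrow,72.5
M,high,red_marrow,2.6e-4
M,low,red_marrow,2.0e-4
M,body,body,1.0e-3
F,red_marrow,red_marrow,94.2
F,high,red_marrow,3.1e-4
F,low,red_marrow,2.5e-4
F,body,body,1.2e-3
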