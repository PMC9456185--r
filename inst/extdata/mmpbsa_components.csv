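replicate,frame,e_vdw,e_ele,g_solv_polar,g_solv_nonpolar
1,1,-35.12,-17.05,29.69,-5.51
2,1,-35.12,-17.05,29.69,-5.51
3,1,-35.12,-17.05,29.69,-5.51
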