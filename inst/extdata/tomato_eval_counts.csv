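variety,phase,n_images,n_main_stems,n_detected,FN,TP,FP,SD
cherry,1,11,11,14,2,9,0,14
cherry,2,17,17,16,5,12,0,16
cherry,3,22,22,33,4,18,1,32
ordinary,1,10,19,18,5,14,1,17
ordinary,2,13,24,21,9,15,0,21
ordinary,3,32,63,78,10,53,3,75
ordinary,4,25,47,48,18,29,5,43
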