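frame,s,point_index,x_um,z_um
1,0,1,8,0
1,0,2,7.39,3.06
1,0,3,5.66,5.66
1,0,4,3.06,7.39
1,0,5,0,8
1,0,6,-3.06,7.39
1,0,7,-5.66,5.66
1,0,8,-7.39,3.06
1,0,9,-8,0
1,0,10,-7.39,-3.06
1,0,11,-5.66,-5.66
1,0,12,-3.06,-7.39
1,0,13,0,-8
1,0,14,3.06,-7.39
1,0,15,5.66,-5.66
1,0,16,7.39,-3.06
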