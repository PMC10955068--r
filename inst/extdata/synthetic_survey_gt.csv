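image_id,x_min,y_min,x_max,y_max
img0001,441.9,189.9,476.7,224.7
img0001,1223,1106.7,1258.5,1142.7
img0001,1244.4,460.5,1284.5,498.6
img0001,90.7,337.8,138,385.4
img0001,983.9,333.4,1032,379.2
img0001,274.2,899.2,318.8,944.4
img0002,963.2,67.4,1003.2,102.8
img0002,340,309.2,388.3,360.8
img0002,308.4,275.2,350.5,317.2
img0002,659.9,694.2,699.6,736.4
img0003,1238.4,145.5,1276.6,181.4
img0003,1099.4,7.7,1140.5,49.9
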