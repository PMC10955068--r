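image_id,x_min,y_min,x_max,y_max,confidence
img0002,659.7,696.6,697,735.7,0.938
img0001,1244.5,459.3,1285.8,498.4,0.918
img0001,1222.2,1112.1,1258.1,1141.4,0.9
img0003,1100.7,8.2,1140.3,46.9,0.895
img0002,966.9,66,1004,104,0.851
img0002,340.3,307.5,388,363.2,0.824
img0002,306.3,278.3,349.9,315.1,0.784
img0001,981,334.4,1032.6,376.4,0.72
img0003,1109,255.2,1163,309.3,0.697
img0001,272.1,900.3,320.6,941.7,0.693
img0001,92.5,336.3,139.4,388.7,0.659
img0003,1240,148.1,1277.6,184.1,0.548
img0003,1016.7,48.6,1062.2,94.1,0.514
img0001,890.6,1031.7,914.6,1055.7,0.362
img0001,645.8,535.9,685.2,575.3,0.342
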