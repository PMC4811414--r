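r,g,b,X,Y,Z
255,255,255,95.0456,100,108.8754
0,0,0,0,0,0
255,0,0,41.2453,21.2671,1.9334
28,68,7,2.58429138315,4.39630559222,0.913345053405
215,46,250,46.2528314973,23.3049426355,92.4786424683
224,219,120,59.4632401012,67.8682718711,27.7317448321
239,195,128,59.009813407,58.9427249969,28.6851292731
196,234,151,57.7725800106,72.8154339576,40.2808616983
101,65,215,19.5182181382,11.452197545,65.4536280033
152,32,17,13.5681757964,7.75104883566,1.3118657301
255,41,139,46.6964062597,24.7161673761,26.7309289633
173,94,125,24.9383669528,18.3721958321,21.6292304275
0,43,37,1.19761514272,1.86117148083,2.04588293564
229,113,79,39.6327292043,29.0374413926,10.912732058
32,208,17,23.251488501,45.4568595799,8.07874870915
177,135,206,37.9331063705,31.1315278764,62.3864885817
237,186,163,59.09550325,55.7695931567,42.2922800372
146,155,136,28.0183110115,31.3312218554,27.8573384072
220,0,2,29.5299457862,15.2251062924,1.44140572088
62,168,213,27.993827253,33.8302059147,67.9873028675
37,38,192,10.9664908249,5.58373210839,50.354694956
23,248,5,33.9463008142,67.3242203602,11.3492521848
143,10,37,11.7714698395,6.19217445952,2.32518027408
183,56,22,21.0897997539,12.9567328252,2.14927469688
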