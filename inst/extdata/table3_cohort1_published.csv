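test_id,sens,sens_lo,sens_hi,spec,spec_lo,spec_hi,ppv,ppv_lo,ppv_hi,npv,npv_lo,npv_hi,delta_sens,delta_sens_lo,delta_sens_hi,p_sens,delta_spec,delta_spec_lo,delta_spec_hi,p_spec,n_pairwise
rmi1@200,48.9,34.1,63.9,95.4,93.4,96.9,44.2,30.5,58.7,96.1,94.3,97.5,-6.4,-15.5,2.7,0.25,1.1,0.1,2.1,0.02,672
rmi1@250,42.6,28.3,57.8,96.5,94.7,97.8,47.6,32.0,63.6,95.7,93.8,97.2,NA,NA,NA,NA,NA,NA,NA,NA,NA
roma@7.4,89.6,77.3,96.5,47.0,43.3,50.8,10.4,7.6,13.7,98.5,96.6,99.5,-47.8,-64.4,-31.2,0.001,49.3,45.0,53.7,0.001,636
roma@11.4,79.2,65.0,89.5,73.1,69.6,76.3,16.7,12.1,22.2,98.1,96.5,99.1,-37.0,-53.1,-20.8,0.001,23.6,19.6,27.5,0.001,636
roma@12.5,77.1,62.7,88.0,68.6,64.4,72.5,18.4,13.3,24.5,97.0,94.7,98.5,-34.8,-50.7,-18.8,0.001,19.8,16.0,23.6,0.001,636
roma@13.1,75.0,60.4,86.4,78.8,75.6,81.7,19.5,14.0,25.9,97.9,96.3,98.9,-32.6,-48.3,-16.9,0.001,17.6,13.9,21.3,0.001,636
adnex@3,93.5,82.1,98.6,45.5,41.4,49.7,12.1,8.9,16.0,98.9,96.7,99.8,-52.2,-68.8,-35.6,0.001,50.8,46.5,55.1,0.001,617
adnex@10,89.1,76.4,96.4,75.1,71.4,78.6,22.4,16.6,29.1,98.8,97.3,99.6,-47.8,-64.4,-31.2,0.001,21.2,17.4,25.0,0.001,617
srrisk@3,87.2,74.3,95.2,62.8,58.9,66.6,15.1,11.0,19.9,98.5,96.7,99.4,-44.7,-61.0,-28.3,0.001,33.6,29.5,37.7,0.001,666
srrisk@10,83.0,69.2,92.4,76.0,72.4,79.3,20.7,15.2,27.2,98.3,96.7,99.3,-40.4,-57.8,-23.1,0.001,20.4,16.6,24.1,0.001,666
simple_rules,75.0,56.6,88.5,95.2,93.0,96.9,49.0,34.4,63.7,98.4,96.9,99.3,-28.1,-49.1,-7.2,0.01,2.3,-0.1,4.7,0.06,551
ca125@87,55.1,40.2,69.3,89.0,86.5,91.2,24.8,17.0,34.0,96.8,95.2,98.0,-10.6,-21.6,0.3,0.06,6.9,4.6,9.2,0.001,672
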