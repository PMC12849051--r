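test_id,model,threshold_label,tp,fp,fn,tn,n_missing_case,n_missing_control,n_inconclusive_case,n_inconclusive_control
rmi1@200,rmi1,>200,23,29,24,596,2,125,0,0
rmi1@250,rmi1,>250,20,22,27,603,2,125,0,0
roma@7.4,roma,>7.4%,43,372,5,330,1,48,0,0
roma@11.4,roma,>11.4%,38,189,10,513,1,48,0,0
roma@12.5,roma,>12.5%,37,164,11,358,1,48,0,0
roma@13.1,roma,>13.1%,36,149,12,553,1,48,0,0
adnex@3,adnex,>3.0%,43,311,3,260,3,179,0,0
adnex@10,adnex,>10.0%,41,142,5,429,3,179,0,0
srrisk@3,srrisk,>3.0%,41,231,6,390,2,129,0,0
srrisk@10,srrisk,>10.0%,39,149,8,472,2,129,0,0
simple_rules,simple_rules,malignant,24,25,8,496,2,124,15,105
ca125@87,ca125,>87 IU/mL,27,82,22,664,0,4,0,0
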