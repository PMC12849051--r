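order,rule_id,category,description
1,no_lesion,1,"No adnexal lesion present: normal ovary"
2,metastases,5,"Peritoneal/omental metastases visible: high risk"
3,ascites_with_solid,5,"Ascites together with a solid-component lesion: high risk"
4,many_papillations,5,"Four or more papillary projections: high risk"
5,irregular_solid,5,"Irregular solid tumour (solid areas with simple rules M1): high risk"
6,solid_component,4,"Any other lesion with solid areas: intermediate risk"
7,papillations_1_3,4,"One to three papillary projections without other high-risk features: intermediate risk"
8,large_multilocular,4,"Multilocular cyst with maximal diameter >= 100 mm: intermediate risk"
9,multilocular,3,"Smooth multilocular cyst < 100 mm, no solid component: low risk"
10,large_unilocular,3,"Unilocular cyst >= 100 mm, no solid component: low risk"
11,simple_small,2,"Unilocular cyst < 100 mm, no solid component, no papillations: almost certainly benign"
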