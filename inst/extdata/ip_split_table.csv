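class,train,val,test,total
Alfalfa,4,4,38,46
Corn-notill,142,128,1158,1428
Corn-mintill,83,74,673,830
Corn,23,21,193,237
Grass-pasture,48,43,392,483
Grass-trees,73,65,592,730
Grass-pasture-mowed,2,2,24,28
Hay-windrowed,47,43,388,478
Oats,2,1,17,20
Soybean-notill,97,87,788,972
Soybean-mintill,245,221,1989,2455
Soybean-clean,59,53,481,593
Wheat,20,18,167,205
Woods,126,113,1026,1265
Buildings-Grass-Trees-Drives,38,34,314,386
Stone-Steel-Towers,9,8,76,93
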