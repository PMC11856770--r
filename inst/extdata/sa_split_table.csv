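class,train,val,test,total
Brocoli_green_weeds_1,20,19,1970,2009
Brocoli_green_weeds_2,37,36,3653,3726
Fallow,19,19,1938,1976
Fallow_rough_plow,13,13,1368,1394
Fallow_smooth,26,26,2626,2678
Stubble,39,39,3881,3959
Celery,35,35,3509,3579
Grapes_untrained,112,111,11048,11271
Soil_vinyard_develop,62,61,6080,6203
Corn_senesced_green_weeds,32,32,3214,3278
Lettuce_romaine_4wk,10,10,1048,1068
Lettuce_romaine_5wk,19,19,1889,1927
Lettuce_romaine_6wk,9,9,898,916
Lettuce_romaine_7wk,10,10,1050,1070
Vinyard_untrained,72,71,7125,7268
Vinyard_vertical_trellis,18,17,1772,1807
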