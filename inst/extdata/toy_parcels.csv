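"parcel_id","landuse","luc_class","area_ha","centroid_x","centroid_y","tenure"
"HW1","Dairy",2,210,500,400,
"HW2","SheepBeef",3,340,1800,600,
"HW3","SheepBeef",5,460,3200,900,
"HW4","Forestry",7,275,4100,1500,
"HW5","SheepBeef",8,150,5200,2100,
"HW6","NativeForest",8,900,6400,2600,"Crown"
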