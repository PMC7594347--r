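animal,breed,trait,value,technician,cg,lab,age_days
A00001,ANGUS,LMA,85.9804230837937,L1T01,L1T01C01,1,364
A00002,ANGUS,LMA,96.0123766147989,L1T01,L1T01C01,1,405
A00003,ANGUS,LMA,75.8028166083993,L1T01,L1T01C01,1,359
A00004,ANGUS,LMA,84.2894761809224,L1T01,L1T01C01,1,447
A00005,ANGUS,LMA,120.651610248826,L1T01,L1T01C02,1,418
A00006,ANGUS,LMA,108.328044223683,L1T01,L1T01C02,1,354
A00007,ANGUS,LMA,92.1082910939581,L1T01,L1T01C02,1,332
A00008,ANGUS,LMA,100.591118164889,L1T01,L1T01C02,1,320
A00009,ANGUS,LMA,86.7717557281553,L1T02,L1T02C01,1,341
A00010,ANGUS,LMA,83.1019478258978,L1T02,L1T02C01,1,404
A00011,ANGUS,LMA,79.3540962388464,L1T02,L1T02C01,1,340
A00012,ANGUS,LMA,80.6944932330607,L1T02,L1T02C01,1,337
A00013,ANGUS,LMA,63.276187922165,L1T02,L1T02C02,1,447
A00014,ANGUS,LMA,75.8824593503298,L1T02,L1T02C02,1,340
A00015,ANGUS,LMA,78.6145430175342,L1T02,L1T02C02,1,354
A00016,ANGUS,LMA,61.4468663899836,L1T02,L1T02C02,1,452
A00017,ANGUS,LMA,89.0958623328723,L2T01,L2T01C01,2,343
A00018,ANGUS,LMA,88.1220670450414,L2T01,L2T01C01,2,448
A00019,ANGUS,LMA,70.9496310324306,L2T01,L2T01C01,2,404
A00020,ANGUS,LMA,66.995959578778,L2T01,L2T01C01,2,344
A00021,ANGUS,LMA,68.5223479275797,L2T01,L2T01C02,2,435
A00022,ANGUS,LMA,91.7505014459911,L2T01,L2T01C02,2,335
A00023,ANGUS,LMA,79.2191479392227,L2T01,L2T01C02,2,415
A00024,ANGUS,LMA,79.6512448502145,L2T01,L2T01C02,2,396
A00025,ANGUS,LMA,114.681469356408,L2T02,L2T02C01,2,381
A00026,ANGUS,LMA,116.420810128043,L2T02,L2T02C01,2,357
A00027,ANGUS,LMA,110.626919322423,L2T02,L2T02C01,2,371
A00028,ANGUS,LMA,110.836724609194,L2T02,L2T02C01,2,343
A00029,ANGUS,LMA,86.1356158475577,L2T02,L2T02C02,2,331
A00030,ANGUS,LMA,83.370041571115,L2T02,L2T02C02,2,391
A00031,ANGUS,LMA,69.9311256053484,L2T02,L2T02C02,2,405
A00032,ANGUS,LMA,71.5580598290726,L2T02,L2T02C02,2,422
A00033,ANGUS,LMA,62.9738659442423,L3T01,L3T01C01,3,450
A00034,ANGUS,LMA,60.9798748291988,L3T01,L3T01C01,3,450
A00035,ANGUS,LMA,51.9437794119055,L3T01,L3T01C01,3,320
A00036,ANGUS,LMA,59.8332154192627,L3T01,L3T01C01,3,334
A00037,ANGUS,LMA,68.4509730355372,L3T01,L3T01C02,3,388
A00038,ANGUS,LMA,62.7332150648508,L3T01,L3T01C02,3,380
A00039,ANGUS,LMA,65.3187746858558,L3T01,L3T01C02,3,401
A00040,ANGUS,LMA,83.5009961506949,L3T01,L3T01C02,3,328
A00041,ANGUS,LMA,87.7789059841239,L3T02,L3T02C01,3,321
A00042,ANGUS,LMA,93.0708491286817,L3T02,L3T02C01,3,346
A00043,ANGUS,LMA,93.3803481173943,L3T02,L3T02C01,3,328
A00044,ANGUS,LMA,89.1397034644253,L3T02,L3T02C01,3,324
A00045,ANGUS,LMA,72.8218863571828,L3T02,L3T02C02,3,402
A00046,ANGUS,LMA,97.288222543501,L3T02,L3T02C02,3,417
A00047,ANGUS,LMA,72.890644093887,L3T02,L3T02C02,3,346
A00048,ANGUS,LMA,68.5731961438228,L3T02,L3T02C02,3,359
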