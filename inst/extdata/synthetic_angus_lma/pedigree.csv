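animal,sire,dam
GS0002,0,0
GS0001,0,0
S0006,0,0
S0002,0,0
S0001,0,0
S0008,0,0
S0007,0,0
S0004,0,0
S0005,0,0
S0003,0,0
GD0001,0,0
GD0002,0,0
GD0003,0,0
GD0004,0,0
GD0005,0,0
GD0006,0,0
GD0007,0,0
GD0008,0,0
GD0009,0,0
GD0010,0,0
GD0011,0,0
GD0012,0,0
GD0013,0,0
GD0014,0,0
GD0015,0,0
GD0016,0,0
GD0017,0,0
GD0018,0,0
GD0019,0,0
GD0020,0,0
D0001,GS0002,GD0001
D0002,GS0002,GD0002
D0003,GS0001,GD0003
D0005,GS0001,GD0004
D0007,GS0002,GD0005
D0008,GS0002,GD0006
D0009,GS0001,GD0007
D0010,GS0001,GD0008
D0011,GS0002,GD0009
D0012,GS0002,GD0010
D0013,GS0002,GD0011
D0014,GS0001,GD0012
D0015,GS0001,GD0013
D0016,GS0002,GD0014
D0017,GS0001,GD0015
D0018,GS0001,GD0016
D0019,GS0001,GD0017
D0020,GS0001,GD0018
D0022,GS0001,GD0019
D0024,GS0002,GD0020
A00004,S0008,D0001
A00013,S0005,D0001
A00021,S0006,D0002
A00042,S0008,D0003
A00018,S0008,D0005
A00023,S0006,D0005
A00026,S0003,D0005
A00002,S0002,D0007
A00008,S0004,D0007
A00014,S0008,D0007
A00024,S0005,D0008
A00029,S0004,D0008
A00030,S0003,D0008
A00032,S0006,D0008
A00035,S0005,D0009
A00036,S0004,D0009
A00005,S0006,D0010
A00012,S0007,D0010
A00028,S0002,D0011
A00031,S0005,D0011
A00033,S0002,D0012
A00034,S0006,D0012
A00038,S0004,D0012
A00041,S0006,D0012
A00045,S0004,D0012
A00009,S0008,D0013
A00017,S0003,D0014
A00020,S0004,D0014
A00043,S0001,D0015
A00044,S0001,D0015
A00046,S0008,D0015
A00048,S0005,D0015
A00003,S0001,D0016
A00016,S0007,D0016
A00022,S0008,D0017
A00025,S0008,D0017
A00039,S0003,D0018
A00001,S0006,D0019
A00007,S0007,D0019
A00010,S0007,D0019
A00019,S0005,D0020
A00027,S0005,D0020
A00006,S0002,D0022
A00011,S0008,D0022
A00015,S0004,D0022
A00037,S0002,D0024
A00040,S0007,D0024
A00047,S0002,D0024
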