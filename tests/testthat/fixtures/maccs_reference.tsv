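smiles	on_bits
CCO	82,109,114,139,153,155,157,160,164
c1ccccc1	162,163,165
CC(=O)Oc1ccccc1C(=O)O	89,113,123,126,127,136,139,140,143,144,146,150,152,154,157,159,160,162,163,164,165
CN1CCC[C@H]1c1cccnc1	62,65,75,80,83,85,86,93,96,98,100,108,111,115,116,118,120,121,122,129,137,142,147,148,150,153,156,158,160,161,162,163,165
Cc1ccc(cc1)S(=O)(=O)N	32,33,51,55,58,59,60,61,64,67,69,73,81,84,88,94,102,106,112,117,124,130,136,148,151,156,159,160,161,162,163,164,165
c1ccc2c(c1)cccc2	101,105,125,145,162,163,165
OCC(O)CO	53,54,72,82,89,90,104,109,131,132,138,139,146,152,153,155,157,159,164
CC(C)Cc1ccc(cc1)C(C)C(=O)O	74,115,123,139,141,149,154,155,157,159,160,162,163,164,165
Clc1ccc(cc1)C(=O)N	84,87,92,103,107,110,117,134,151,154,156,158,161,162,163,164,165
CCN(CC)CC	85,86,100,114,116,122,138,141,148,149,153,155,158,160,161
C1CCNCC1	82,86,90,91,98,100,104,111,118,121,128,129,137,138,147,151,153,158,161,163,165
O=[N+]([O-])c1ccccc1	24,49,56,63,70,71,94,102,119,122,124,130,133,135,148,156,158,159,161,162,163,164,165
NCCc1ccccc1	82,84,100,104,111,118,147,151,153,155,158,161,162,163,165
CC(=O)NC	92,93,110,117,149,151,154,156,158,160,161,164
FC(F)(F)c1ccccc1	42,106,107,112,134,162,163,165
CSCC	86,88,93,114,115,149,153,155,160
OC(=O)CCC(=O)O	90,104,118,123,131,132,136,139,140,146,147,154,155,157,159,164
c1ccoc1	57,83,96,137,162,164,165
c1ccsc1	36,83,88,96,137,162,165
CNC(=N)N	25,43,77,78,84,93,106,119,131,142,151,156,158,160,161
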