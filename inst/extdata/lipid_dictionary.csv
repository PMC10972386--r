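name,subclass,class,formula,adducts,fragment_formulas
Car(16:0),Car,fatty acid,C23H45NO4,[M+H]+,C4H5O2+
Car(16:1),Car,fatty acid,C23H43NO4,[M+H]+,C4H5O2+
Car(17:0),Car,fatty acid,C24H47NO4,[M+H]+,C4H5O2+
Car(18:1),Car,fatty acid,C25H47NO4,[M+H]+,C4H5O2+
FFA(14:0),FFA,fatty acid,C14H28O2,[M-H]-,C14H27O2-
FFA(16:0),FFA,fatty acid,C16H32O2,[M-H]-,C16H31O2-
FFA(16:1),FFA,fatty acid,C16H30O2,[M-H]-,C16H29O2-
FFA(17:0),FFA,fatty acid,C17H34O2,[M-H]-,C17H33O2-
FFA(17:1),FFA,fatty acid,C17H32O2,[M-H]-,C17H31O2-
FFA(18:0),FFA,fatty acid,C18H36O2,[M-H]-,C18H35O2-
FFA(18:2),FFA,fatty acid,C18H32O2,[M-H]-,C18H31O2-
FFA(18:3),FFA,fatty acid,C18H30O2,[M-H]-,C18H29O2-
FFA(20:0),FFA,fatty acid,C20H40O2,[M-H]-,C20H39O2-
FFA(22:2),FFA,fatty acid,C22H40O2,[M-H]-,C22H39O2-
FFA(22:4),FFA,fatty acid,C22H36O2,[M-H]-,C22H35O2-
FFA(22:6),FFA,fatty acid,C22H32O2,[M-H]-,C22H31O2-
FFA(23:0),FFA,fatty acid,C23H46O2,[M-H]-,C23H45O2-
FFA(28:0),FFA,fatty acid,C28H56O2,[M-H]-,C28H55O2-
DG(34:1),DG,glycerolipid,C37H70O5,[M+NH4]+,C37H69O4+
DG(36:1),DG,glycerolipid,C39H74O5,[M+NH4]+,C39H73O4+
DG(40:6),DG,glycerolipid,C43H72O5,[M+NH4]+,C43H71O4+
PA(34:1),PA,glycerolipid,C37H71O8P,[M-H]-,C3H6O5P-
PA(36:2),PA,glycerolipid,C39H73O8P,[M-H]-,C3H6O5P-
PG(34:1),PG,glycerolipid,C40H77O10P,[M-H]-,C3H6O5P-
PG(36:2),PG,glycerolipid,C42H79O10P,[M-H]-,C3H6O5P-
TG(36:2),TG,glycerolipid,C39H70O6,[M+NH4]+,C39H69O5+
TG(48:1),TG,glycerolipid,C51H96O6,[M+NH4]+,C51H95O5+
TG(52:3),TG,glycerolipid,C55H100O6,[M+NH4]+,C55H99O5+
TG(54:4),TG,glycerolipid,C57H102O6,[M+NH4]+,C57H101O5+
TG(54:5),TG,glycerolipid,C57H100O6,[M+NH4]+,C57H99O5+
TG(58:9),TG,glycerolipid,C61H100O6,[M+NH4]+,C61H99O5+
CL(72:6),CL,phospholipid,C81H146O17P2,[M-H]-,C3H6O5P-
CL(72:8),CL,phospholipid,C81H142O17P2,[M-H]-,C3H6O5P-
LPC(16:0),LPC,phospholipid,C24H50NO7P,[M+H]+,C5H15NO4P+
LPC(18:1),LPC,phospholipid,C26H52NO7P,[M+H]+,C5H15NO4P+
LPE(20:4),LPE,phospholipid,C25H44NO7P,[M-H]-,C5H11NO5P-
LPE(22:6),LPE,phospholipid,C27H44NO7P,[M-H]-,C5H11NO5P-
PC(30:0),PC,phospholipid,C38H76NO8P,[M+H]+,C5H15NO4P+
PC(32:0),PC,phospholipid,C40H80NO8P,[M+H]+,C5H15NO4P+
PC(34:1),PC,phospholipid,C42H82NO8P,[M+H]+,C5H15NO4P+
PC(36:3),PC,phospholipid,C44H82NO8P,[M+H]+,C5H15NO4P+
PC(37:3),PC,phospholipid,C45H84NO8P,[M+H]+,C5H15NO4P+
PC(38:2),PC,phospholipid,C46H88NO8P,[M+H]+,C5H15NO4P+
PC(40:8),PC,phospholipid,C48H80NO8P,[M+H]+,C5H15NO4P+
PC(41:1),PC,phospholipid,C49H96NO8P,[M+H]+,C5H15NO4P+
PC(41:7),PC,phospholipid,C49H84NO8P,[M+H]+,C5H15NO4P+
PC(O-37:5),PC,phospholipid,C45H82NO7P,[M+H]+,C5H15NO4P+
PC(O-38:4),PC,phospholipid,C46H86NO7P,[M+H]+,C5H15NO4P+
PC(O-38:5),PC,phospholipid,C46H84NO7P,[M+H]+,C5H15NO4P+
PE(34:1),PE,phospholipid,C39H76NO8P,[M-H]-,C5H11NO5P-
PE(36:2),PE,phospholipid,C41H78NO8P,[M-H]-,C5H11NO5P-
PE(36:3),PE,phospholipid,C41H76NO8P,[M-H]-,C5H11NO5P-
PE(38:4),PE,phospholipid,C43H78NO8P,[M-H]-,C5H11NO5P-
PE(42:10),PE,phospholipid,C47H74NO8P,[M-H]-,C5H11NO5P-
PE(O-16:1/20:3),PE,phospholipid,C41H76NO7P,[M-H]-,C5H11NO5P-
PE(O-32:1),PE,phospholipid,C37H74NO7P,[M-H]-,C5H11NO5P-
PE(O-38:5),PE,phospholipid,C43H78NO7P,[M-H]-,C5H11NO5P-
PE(O-40:1),PE,phospholipid,C45H90NO7P,[M-H]-,C5H11NO5P-
PE(O-40:5),PE,phospholipid,C45H82NO7P,[M-H]-,C5H11NO5P-
PE(O-40:7),PE,phospholipid,C45H78NO7P,[M-H]-,C5H11NO5P-
PE(O-42:7),PE,phospholipid,C47H82NO7P,[M-H]-,C5H11NO5P-
PI(34:1),PI,phospholipid,C43H81O13P,[M-H]-,C6H10O8P-
PI(38:4),PI,phospholipid,C47H83O13P,[M-H]-,C6H10O8P-
PI(40:6),PI,phospholipid,C49H83O13P,[M-H]-,C6H10O8P-
PS(36:1),PS,phospholipid,C42H80NO10P,[M-H]-,C3H6O5P-
PS(38:4),PS,phospholipid,C44H78NO10P,[M-H]-,C3H6O5P-
PS(40:5),PS,phospholipid,C46H80NO10P,[M-H]-,C3H6O5P-
PS(40:6),PS,phospholipid,C46H78NO10P,[M-H]-,C3H6O5P-
PS(O-40:7),PS,phospholipid,C46H78NO9P,[M-H]-,C3H6O5P-
Cer(d34:1),Cer,sphingolipid,C34H67NO3,[M+H]+,C18H34N+
Cer(d36:1),Cer,sphingolipid,C36H71NO3,[M+H]+,C18H34N+
Cer(d36:2),Cer,sphingolipid,C36H69NO3,[M+H]+,C18H34N+
Cer(d38:2),Cer,sphingolipid,C38H73NO3,[M+H]+,C18H34N+
Cer(d41:0),Cer,sphingolipid,C41H83NO3,[M+H]+,C18H34N+
Cer(d42:2),Cer,sphingolipid,C42H81NO3,[M+H]+,C18H34N+
HexCer(d34:1),HexCer,sphingolipid,C40H77NO8,[M+H]+,C18H34N+
HexCer(d36:1),HexCer,sphingolipid,C42H81NO8,[M+H]+,C18H34N+
HexCer(d42:2),HexCer,sphingolipid,C48H91NO8,[M+H]+,C18H34N+
SGL(d34:1),SGL,sphingolipid,C40H77NO11S,[M-H]-,HO4S-
SGL(d36:1),SGL,sphingolipid,C42H81NO11S,[M-H]-,HO4S-
SGL(d42:2),SGL,sphingolipid,C48H91NO11S,[M-H]-,HO4S-
SM(d34:1),SM,sphingolipid,C39H79N2O6P,[M+H]+,C5H15NO4P+
SM(d36:1),SM,sphingolipid,C41H83N2O6P,[M+H]+,C5H15NO4P+
SM(d36:2),SM,sphingolipid,C41H81N2O6P,[M+H]+,C5H15NO4P+
SM(d38:1),SM,sphingolipid,C43H87N2O6P,[M+H]+,C5H15NO4P+
SM(d42:2),SM,sphingolipid,C47H93N2O6P,[M+H]+,C5H15NO4P+
sphingosine(d18:1),sphingoid base,sphingolipid,C18H37NO2,[M+H]+,C18H34N+
sphingosine(d16:1),sphingoid base,sphingolipid,C16H33NO2,[M+H]+,C18H34N+
sphinganine(d18:0),sphingoid base,sphingolipid,C18H39NO2,[M+H]+,C18H34N+
tetradecanedioic acid,FFA,fatty acid,C14H26O4,[M-H]-,C14H25O4-
DG(16:0_22:4),DG,glycerolipid,C41H72O5,[M+NH4]+,C41H71O4+
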