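filament_id,fed_successfully,ABS,Dissolvable,PLA,reported_average,reported_rounded
HPMCAS,N,0.38,0.64,0.18,0.40,0
Mowiflex,Y,0.76,0.69,0.74,0.73,1
PEO,Y,0.92,0.71,0.82,0.82,1
PVPVA64,N,-0.08,0.22,-0.12,0.01,0
Soluplus,N,-0.56,0.40,-0.75,-0.30,0
EudragitEPO,N,-0.70,0.30,-0.79,-0.40,0
EUD,Y,0.94,0.65,0.88,0.82,1
HD,N,0.32,0.60,0.18,0.37,0
HP10,Y,0.85,0.82,0.67,0.78,1
HP10D,Y,0.96,0.53,0.94,0.81,1
HP20,Y,0.94,0.70,0.87,0.84,1
HP20D,Y,0.90,0.48,0.95,0.78,1
HP30,Y,0.95,0.77,0.89,0.87,1
HP30D,Y,0.91,0.40,0.94,0.75,1
HP70,Y,0.70,0.73,0.51,0.65,1
HP90,Y,0.81,0.81,0.74,0.79,1
SP,N,0.49,0.63,0.28,0.47,0
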