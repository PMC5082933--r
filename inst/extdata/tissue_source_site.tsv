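code	name
A1	Breast Cancer Source Site 1
A2	Breast Cancer Source Site 2
A7	Christiana Healthcare
AR	Mayo Clinic Rochester
BH	University of Pittsburgh
E2	Roswell Park
02	MD Anderson Cancer Center
06	Henry Ford Hospital
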