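raw_name	canonical_name
University of Pittsburgh	University of Pittsburgh
Univ. of Pittsburgh	University of Pittsburgh
University of Pittsburg	University of Pittsburgh
university  of pittsburgh	University of Pittsburgh
University-of-Pittsburgh	University of Pittsburgh
MD Anderson Cancer Center	MD Anderson Cancer Center
M.D. Anderson Cancer Center	MD Anderson Cancer Center
MD Anderson	MD Anderson Cancer Center
MD-Anderson Cancer Center	MD Anderson Cancer Center
Mayo Clinic Rochester	Mayo Clinic Rochester
Mayo Clinic - Rochester	Mayo Clinic Rochester
Mayo Clinic  Rochester	Mayo Clinic Rochester
Roswell Park	Roswell Park
Roswel Park	Roswell Park
Roswell  Park	Roswell Park
Christiana Healthcare	Christiana Healthcare
Christiana Health Care	Christiana Healthcare
Henry Ford Hospital	Henry Ford Hospital
Henry-Ford Hospital	Henry Ford Hospital
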