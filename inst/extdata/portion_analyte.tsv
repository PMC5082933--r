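code	name
D	DNA
G	Whole Genome Amplification (WGA) produced using GenomiPhi (Qiagen) DNA
H	mirVana RNA (Allprep DNA) produced by hybrid protocol
R	RNA
T	Total RNA
W	Whole Genome Amplification (WGA) produced using Repli-G (Qiagen) DNA
X	Whole Genome Amplification (WGA) produced using Repli-G X (Qiagen) DNA (2nd reaction)
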