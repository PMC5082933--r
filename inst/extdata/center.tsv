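code	name
01	broad.mit.edu
02	hms.harvard.edu
03	lbl.gov
04	mskcc.org
05	genome.wustl.edu
07	unc.edu
08	usc.edu
09	bcgsc.ca
10	baylor.edu
13	bcgsc.ca_miRNA
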