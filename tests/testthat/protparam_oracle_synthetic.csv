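id,sequence,mw,pi,eps280_reduced,eps280_cystine
pep01,AKIIFEVDWQCADHITYAVHVQIRWKAGQM,3558.0965,6.9522,12490,12490
pep02,FHMEDPENNYKCRVEPDVLYNWHDCILDIEPKRNGNNHKDYGVIGRPKVI,5982.6575,5.8215,9970,10095
pep03,CICMPKDHWMHSPRFKFIVVKWQWPNIFTSDCEFGQYDPPYRTKVAEVKM,6122.1304,8.5793,19480,19605
pep04,LQGRAKTGTELTYHFNGVTAYMSAENLICI,3302.7336,6.746,2980,2980
pep05,DSDVFFSVGKTYQHVHLPNRTREIIDMAWV,3561.9759,6.0076,6990,6990
pep06,WIADCIDCMDTIKSHVFWWSISQHEEQNQQ,3679.0362,4.4186,16500,16625
pep07,CECPMEIHHVRFQGKRIDRVECVADIGQSSHPCGPAPKRLQVSFHLHCWV,5738.617,7.8728,5500,5750
pep08,HMIKPFLRMDARYWEDVHTKFNDINLGRVLYTAVLEFKEEVFKLYHMHKT,6212.1884,8.2993,9970,9970
pep09,KCDQKCAMFKGRVQVAEDFVCNWVFQFCLNCNHIENVQYFIGGQAGMQIK,5790.7008,7.8172,6990,7240
pep10,EPCSIHRNLIIAHPMKDKNTPVMAEKGWKC,3448.0724,8.8362,5500,5625
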