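>tr|A0A087RZB5|A0A087RZB5_9ARCH Matrix metalloproteinase-1 interstitial collagenase OS=Marine Group I thaumarchaeote SCGC AAA799-P11 OX=1502295 GN=AAA799P11_00940 PE=4 SV=1
MLQKKSDEFEQLYEKYDKLKMKVKELSQENQIYSHMCKKIETNSKDLKKSQSNLKKQLDQ
KLHSQLESEQEKLLLEKQLERSESSSKKSQKKYYVALVMAALSIAIISGAYSIMFAELAG
QQYKIEVTPKPTGYTIQNLRGDTINTFLSWRLVPGDTLRVNIINSDNYDPEKIEVIKKTI
LSEKQLEIDNSLMHKGPKGTTSILYEGWLGALNDASKTDTNLFVPTNIEVIESNNGEGDI
TIELTNRKNADGFAGWTNSIADDSQNQILKSRITIFAVDSLSLAELETIVRHEMGHALGL
AHSTDPEDLMYPTIQTNFPYISECDVDAIESLYDGQNTSEVICEI
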