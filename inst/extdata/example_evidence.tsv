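cds_id	source	member_database	description	e_value	identity_pct	score
CALS8_0437	PSI_BLAST		glycoside hydrolase family 43 beta-xylosidase	1e-75	62.5	210
CALS8_0437	BLASTO		beta-xylosidase glycoside hydrolase 43	1e-60	58.0	180
CALS8_0437	PFAM		glycosyl hydrolase family 43	2e-18	NA	95
CALS8_0437	INTERPROSCAN	PFAM	glycosyl hydrolase family 43	1e-19	NA	90
CALS8_0437	ANNIE		beta-xylosidase	1e-30	NA	70
CALS8_0732	PFAM		FMN-binding domain	5e-09	NA	40
CALS8_0732	INTERPROSCAN	GENE3D	FMN-binding split barrel	2e-08	NA	38
CALS8_0999	PSI_BLAST		hypothetical protein	1e-10	25.0	45
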