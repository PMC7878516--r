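name	seq_a	seq_b	orientation	group	variant
P1SN:P2SN	SPNAALEQEIAALEQEIAALEQEIAALEQEGY	SPNAALKQKIAALKQKIAALKQKIAALKQKGY	parallel	pg1	SN
P3SN:P4SN	SPIAALEQENAALEQEIAALEQEIAALEQEGY	SPIAALKQKNAALKQKIAALKQKIAALKQKGY	parallel	pg2	SN
P5SN:P6SN	SPIAALEQEIAALEQENAALEQEIAALEQEGY	SPIAALKQKIAALKQKNAALKQKIAALKQKGY	parallel	pg3	SN
P7SN:P8SN	SPIAALESEIAALESEIAALESENAALESEGY	SPIAALKSKIAALKSKIAALKSKNAALKSKGY	parallel	pg4	SN
P9SN:P10SN	SPIAALESENAALESEIAALESEIAALESEGY	SPIAALKSKNAALKSKIAALKSKIAALKSKGY	parallel	pg5	SN
P11SN:P12SN	SPIAALETEIAALETENAALETEIAALETEGY	SPIAALKTKIAALKTKNAALKTKIAALKTKGY	parallel	pg6	SN
P5SH:P6SH	SPIKELEQEIKELEQENKELEQEIKELEQEGY	SPIKELKQKIKELKQKNKELKQKIKELKQKGY	parallel	pg3	SH
P7SH:P8SH	SPIKELESEIKELESEIKELESENKELESEGY	SPIKELKSKIKELKSKIKELKSKNKELKSKGY	parallel	pg4	SH
P9SH:P10SH	SPIKELESENKELESEIKELESEIKELESEGY	SPIKELKSKNKELKSKIKELKSKIKELKSKGY	parallel	pg5	SH
P11SH:P12SH	SPIKELETEIKELETENKELETEIKELETEGY	SPIKELKTKIKELKTKNKELKTKIKELKTKGY	parallel	pg6	SH
APHSN:APHSN	SPIAALEQKIAALKQEIAALEQKIAALKQEGY	SPIAALEQKIAALKQEIAALEQKIAALKQEGY	antiparallel	aph	SN
BCR:BCR	SPIAALESKIAALKSEIAALESKIAALKSEGY	SPIAALESKIAALKSEIAALESKIAALKSEGY	antiparallel	bcr	SN
BCRSH:BCRSH	SPIKELESKIKELKSEIKELESKIKELKSEGY	SPIKELESKIKELKSEIKELESKIKELKSEGY	antiparallel	bcr	SH
GCNSN:GCNSN	SPVAALEQKVAALEQKVAALEQKVAALEQKGY	SPVAALEQKVAALEQKVAALEQKVAALEQKGY	parallel	gcn	SN
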