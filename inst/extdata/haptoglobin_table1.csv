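site_id,entry
Asn184,"4-5-0-0, 2 Isomers"
Asn184,"4-5-1-1"
Asn184,"4-5-1-2"
Asn184,"4-5-0-1"
Asn184,"4-5-0-2"
Asn184,"4-6-0-1"
Asn184,"5-6-1-1"
Asn184,"5-6-1-2"
Asn184,"5-6-1-3"
Asn184,"5-6-0-1"
Asn184,"5-6-0-2, 2 Isomers"
Asn207,"3-4-0-1, 2 Isomers"
Asn207,"4-4-0-1, 3 Isomers"
Asn207,"4-5-0-0, 2 Isomers"
Asn207,"4-5-1-1, 2 Isomers"
Asn207,"4-5-1-2, 2 Isomers"
Asn207,"4-5-0-1"
Asn207,"4-5-0-2, 2 Isomers"
Asn207,"5-6-1-1, 2 Isomers"
Asn207,"5-6-1-2, 2 Isomers"
Asn207,"5-6-1-3, 2 Isomers"
Asn207,"5-6-0-1, 2 Isomers"
Asn207,"5-6-0-2, 2 Isomers"
Asn207,"5-6-0-3, 3 Isomers"
Asn207,"6-7-1-1, 4 Isomers"
Asn207,"6-7-1-2, 3 Isomers"
Asn207,"6-7-1-3, 5 Isomers"
Asn207,"6-7-0-1"
Asn207,"6-7-0-2, 3 Isomers"
Asn241,"4-4-0-1"
Asn241,"4-5-0-0"
Asn241,"4-5-1-2, 2 Isomers"
Asn241,"4-5-0-1"
Asn241,"4-5-0-2"
Asn241,"5-6-1-2"
Asn241,"5-6-0-1"
Asn241,"5-6-0-2"
Asn241,"5-6-0-3, 3 Isomers"
Asn241,"6-7-0-1"
Asn241,"6-7-0-2"
Asn241,"6-7-0-3, 2 Isomers"
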