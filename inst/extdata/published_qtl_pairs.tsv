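trait	snp_id	chrom	position_bp	validation_position_bp	source
AFI	ss86278343	11	5660631	5205392	external_study_A
AFI	ss117964737	14	70097610	70531680	external_study_B
AFI	ss86295351	15	61349658	60933014	external_study_A
AFI	ss61538007	17	29240631	28901000	external_study_B
AFI	ss86318895	19	49810291	49675000	external_study_B
AFI	ss86339752	21	31529569	31455000	external_study_B
RFI	ss61489474	3	7649578	7401859	external_study_B
RFI	ss86274086	5	35900142	36024610	external_study_B
RFI	ss86290408	6	105402482	105500454	external_study_A
RFI	ss86341687	12	72395434	72497300	external_study_B
RFI	ss86295351	15	61349658	60933014	external_study_A
RFI	ss61538007	17	29240631	28901000	external_study_B
RFI	ss86303118	21	30983757	31455000	external_study_B
ADG	ss86335501	5	33048112	33304000	external_study_B
ADG	ss86298158	17	12720160	12588370	external_study_B
ADG	ss86289007	24	4017728	4153065	external_study_B
ADG	ss61547771	24	52914946	52746000	external_study_B
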